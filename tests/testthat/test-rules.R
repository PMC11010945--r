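test_that("threshold rules follow the published cutoffs", {
  # the standard 1.6x brain rule
  expect_identical(
    applyThresholdRule(1.7, thresholdRule("tbr_brain_10", 1.6)), "tumor")
  # strict boundary: exactly at the cutoff is not tumor
  expect_identical(
    applyThresholdRule(1.0, thresholdRule("tbr_plexus_roimean_10", 1.0)),
    "astrogliosis")
  # late plexus threshold 1.2
  expect_identical(
    applyThresholdRule(1.3, thresholdRule("tbr_plexus_60", 1.2)), "tumor")
  # inclusive variant fires at the boundary
  expect_identical(
    applyThresholdRule(1.0, thresholdRule("x", 1.0, inclusive = TRUE)),
    "tumor")
  expect_error(
    applyThresholdRule(data.frame(a = 1), thresholdRule("b", 1)),
    "unknown feature")
  expect_error(thresholdRule("x", -1))
})

test_that("threshold rules are monotone in the feature", {
  rule <- thresholdRule("x", 1.45)
  v <- sort(runif(50, 0.5, 3))
  lab <- applyThresholdRule(v, rule)
  # once tumor, always tumor as the value rises
  expect_true(all(diff(lab == "tumor") >= 0))
})

test_that("the dual plexus rule is the disjunction of the two timepoints", {
  mk <- function(p10, p60) data.frame(tbr_plexus_10 = p10,
                                      tbr_plexus_60 = p60)
  expect_identical(dualPlexusRule(mk(1.2, 1.0)), "tumor")    # early fires
  expect_identical(dualPlexusRule(mk(0.9, 1.3)), "tumor")    # late fires
  expect_identical(dualPlexusRule(mk(0.9, 1.0)), "astrogliosis")
  expect_error(dualPlexusRule(data.frame(tbr_plexus_10 = 1)),
               "tbr_plexus_60")
  # the dual rule can only gain sensitivity over either single rule
  set.seed(2)
  p10 <- runif(100, 0.5, 2)
  p60 <- runif(100, 0.5, 2)
  dual <- dualPlexusRule(mk(p10, p60)) == "tumor"
  late <- applyThresholdRule(p60, thresholdRule("x", 1.2)) == "tumor"
  expect_true(all(dual[late]))
})

test_that("the published tree reproduces its worked examples", {
  expect_identical(publishedTreeClassify(2.0, 1.5), "tumor")
  expect_identical(publishedTreeClassify(1.5, 1.0), "tumor")
  expect_identical(publishedTreeClassify(0.9, 5.0), "astrogliosis")
  # boundary conventions: 1.77 belongs to the middle branch, 1.05 does not
  expect_identical(publishedTreeClassify(1.77, 0.5), "tumor")
  expect_identical(publishedTreeClassify(1.77, 4.0), "astrogliosis")
  expect_identical(publishedTreeClassify(1.05, 0.5), "astrogliosis")
  # high branch needs the module above 1.11
  expect_identical(publishedTreeClassify(2.0, 1.0), "astrogliosis")
  expect_error(publishedTreeClassify(-1, 1), "non-negative")
})

test_that("the published tree partitions the plane", {
  g <- expand.grid(t = seq(0, 4, by = 0.1), m = seq(0, 5, by = 0.1))
  lab <- publishedTreeClassify(g$t, g$m)
  expect_identical(length(lab), nrow(g))
  expect_true(all(lab %in% c("tumor", "astrogliosis")))
})

test_that("thalamus rules follow the absolute and relative thresholds", {
  # relative, late: inclusive at 1.6
  expect_identical(thalamusRule(1.6, "T60", "relative"), "pathological")
  expect_identical(thalamusRule(1.59, "T60", "relative"), "normal")
  expect_identical(thalamusRule(1.7, "T10", "relative"), "pathological")
  # absolute, late: strict at 1.1
  expect_identical(thalamusRule(1.05, "T60", "absolute"), "normal")
  expect_identical(thalamusRule(1.15, "T60", "absolute"), "pathological")
  expect_identical(thalamusRule(1.01, "T10", "absolute"), "pathological")
  expect_identical(thalamusRule(0, "T10", "absolute"), "normal")
  expect_error(thalamusRule(1, "T10", "nope"))
  expect_error(thalamusRule(-1, "T10", "absolute"), "non-negative")
})
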