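test_that("AUC equals the brute-force pair count on small instances", {
  # perfectly separated scores
  r <- rocAnalysis(c(0.5, 0.6, 1.5, 1.6), c(0, 0, 1, 1))
  expect_equal(auc(r), 1)
  expect_gt(r@youden, 0.6)
  expect_lt(r@youden, 1.5)
  # an interleaved case, frozen from the pair-count oracle
  expect_equal(auc(rocAnalysis(c(1, 3, 2, 4), c(0, 0, 1, 1))), 0.75)
  expect_equal(bruteForceAUC(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)),
               0.75)
  # all scores equal: everything ties, AUC one half
  expect_equal(auc(rocAnalysis(rep(2, 6), c(0, 1, 0, 1, 0, 1))), 0.5)
  expect_error(rocAnalysis(1:4, c(1, 1, 1, 1)), "degenerate labels")

  for (rep in 1:50) {
    set.seed(rep)
    n <- sample(4:50, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    r <- rocAnalysis(scores, pos)
    expect_equal(auc(r), bruteForceAUC(scores, pos), tolerance = 1e-12)
    # curve monotonicity along the cutoffs
    expect_true(all(diff(r@sensitivity) <= 1e-12))
    expect_true(all(diff(r@specificity) >= -1e-12))
  }
})

test_that("the Youden cutoff matches the exhaustive scan", {
  for (rep in 1:30) {
    set.seed(rep + 500)
    n <- sample(4:40, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n, 0, 3), 1)
    r <- rocAnalysis(scores, pos)
    expect_equal(r@youden, bruteForceYouden(scores, pos))
    # no candidate beats the returned cutoff
    J <- r@sensitivity + r@specificity - 1
    at <- which(r@thresholds == r@youden)
    expect_gte(J[at], max(J) - 1e-12)
  }
  # single positive above a single negative: J = 1
  r <- rocAnalysis(c(1, 2), c(0, 1))
  expect_equal(r@sensitivity[r@thresholds == r@youden] +
                 r@specificity[r@thresholds == r@youden] - 1, 1)
})

test_that("ROC is invariant under strictly increasing transforms", {
  set.seed(77)
  scores <- runif(40, 0.2, 4)
  pos <- runif(40) > 0.4
  a <- rocAnalysis(scores, pos)
  b <- rocAnalysis(log(scores), pos)
  c <- rocAnalysis(scores^3, pos)
  expect_equal(auc(a), auc(b))
  expect_equal(auc(a), auc(c))
})

test_that("DeLong and bootstrap intervals bracket the AUC", {
  set.seed(12)
  scores <- c(rnorm(40, 1), rnorm(40, 2))
  pos <- rep(c(FALSE, TRUE), each = 40)
  d <- rocAnalysis(scores, pos, ciMethod = "delong")
  expect_lte(d@ciLow, auc(d))
  expect_gte(d@ciHigh, auc(d))
  b <- rocAnalysis(scores, pos, ciMethod = "bootstrap", bootN = 200)
  expect_lte(b@ciLow, auc(b))
  expect_gte(b@ciHigh, auc(b))
  # the two interval methods roughly agree on a well-behaved instance
  expect_lt(abs(d@ciLow - b@ciLow), 0.1)
})

test_that("confusion metrics count exactly", {
  perfect <- confusionMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  inverted <- confusionMetrics(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)

  # counts chosen near the published first-row rates
  labels <- rep(c(1, 0), c(230, 54))
  preds <- c(rep(1, 213), rep(0, 17), rep(1, 34), rep(0, 20))
  m <- confusionMetrics(labels, preds)
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(213L, 17L, 34L, 20L))
  expect_equal(m$sensitivity, 213 / 230)
  expect_equal(m$specificity, 20 / 54)
  expect_error(confusionMetrics(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("metricsFromRates is Bayes-consistent with confusion counts", {
  expect_equal(metricsFromRates(1, 1, 10, 10), list(ppv = 1, npv = 1))
  sym <- metricsFromRates(0.8, 0.8, 100, 100)
  expect_equal(sym$ppv, 0.8)
  expect_equal(sym$npv, 0.8)
  # published plexus-ROI-mean early row: PPV near the printed 0.90
  pv <- metricsFromRates(0.95, 0.58, 230, 54)
  expect_lt(abs(pv$ppv - 0.90), 0.02)
  expect_error(metricsFromRates(0, 1, 10, 10), "undefined predictive value")
  expect_error(metricsFromRates(1.2, 0.5, 10, 10))

  # round trip: rates from counts reproduce the original PPV/NPV exactly
  set.seed(9)
  labels <- runif(200) > 0.4
  preds <- runif(200) > 0.5
  m <- confusionMetrics(labels, preds)
  pv2 <- metricsFromRates(m$sensitivity, m$specificity,
                          sum(labels), sum(!labels))
  expect_equal(pv2$ppv, m$ppv)
  expect_equal(pv2$npv, m$npv)
})

test_that("paired ROC comparison behaves at its boundaries", {
  set.seed(15)
  labels <- rep(c(0, 1), each = 30)
  s <- c(rnorm(30, 0), rnorm(30, 1))
  same <- compareROCPaired(s, s, labels)
  expect_equal(same$aucDiff, 0)
  expect_equal(same$pValue, 1)

  noise <- rnorm(60)
  ab <- compareROCPaired(s, noise, labels)
  ba <- compareROCPaired(noise, s, labels)
  expect_equal(ab$pValue, ba$pValue)
  expect_equal(ab$aucA, ba$aucB)

  # a separating score beats pure noise decisively at n = 200
  hits <- 0
  for (rep in 1:20) {
    set.seed(rep + 900)
    lab <- rep(c(0, 1), each = 100)
    good <- c(rnorm(100, 0, 0.3), rnorm(100, 3, 0.3))
    rand <- rnorm(200)
    if (compareROCPaired(good, rand, lab)$pValue < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
  expect_error(compareROCPaired(1:4, 1:4, rep(1, 4)), "degenerate")
})

test_that("the contingency summary reproduces the cohort table", {
  cs <- contingencySummary(cohortSamples())
  expect_identical(cs$nTotal, 284L)
  expect_identical(cs$nTumor, 230L)
  expect_equal(unname(cs$counts["astrogliosis", "FLAIR"]), 38)
  expect_equal(unname(cs$percent["astrogliosis", "FLAIR"]), 53)
  expect_equal(unname(cs$percent["G3", "Overall"]), 44)

  single <- contingencySummary(
    data.frame(trajectory = "PET", histology = "G3"))
  expect_equal(unname(single$percent["G3", "Overall"]), 100)
})
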