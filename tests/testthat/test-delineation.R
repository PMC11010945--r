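test_that("tbrMap divides elementwise and is scale invariant", {
  v <- uniformVolume(0.96, dims = c(6, 6, 6))
  expect_true(all(tbrMap(v, 1) == 0.96))
  expect_true(all(abs(tbrMap(v, 0.60) - 1.6) < 1e-12))
  doubled <- uniformVolume(1.92, dims = c(6, 6, 6))
  expect_equal(tbrMap(doubled, 1.20), tbrMap(v, 0.60))
  expect_error(tbrMap(v, 0), "invalid background")
})

test_that("delineation rules threshold against panel backgrounds", {
  # a flat phantom at background level yields an empty mask
  flat10 <- uniformVolume(0.60, dims = c(12, 12, 12), voxelSize = 2,
                          timepoint = "T10")
  flat60 <- uniformVolume(0.74, dims = c(12, 12, 12), voxelSize = 2,
                          timepoint = "T60")
  vals <- stats::setNames(rep(1, 16), fetquant:::.PANEL_ENTRIES)
  vals[c("brain_mean_10", "brain_mean_60")] <- c(0.60, 0.74)
  vals[c("brain_max_10", "brain_max_60")] <- c(1.05, 1.17)
  vals[c("plexus_mean_10", "plexus_max_10")] <- 1.07
  vals[c("plexus_mean_60", "plexus_max_60")] <- 0.91
  pan <- ReferencePanel(vals)
  for (m in c("brain16_standard", "plexus_mean_early_10", "plexus_late_12",
              "dual_plexus"))
    expect_equal(volumeMl(delineate(flat10, flat60, pan, m)), 0)

  # a noise-free median phantom: the G3 core exceeds the early plexus mean
  ph <- generatePhantom(defaultPhantomSpec(noiseSd = 0, seed = 1),
                        medianUptakeModel())
  panPh <- measureReferencePanel(ph$vol10, ph$vol60,
                                 defaultPlacements(ph$spec))
  mask <- delineate(ph$vol10, ph$vol60, panPh, "plexus_mean_early_10")
  core <- ph$tissueLevels[ph$labels] == "G3"
  expect_true(all(mask@mask[core]))  # 1.96 / 1.07 > 1.0
  # provenance records the backgrounds in force
  expect_equal(unname(mask@provenance$background), 1.07)
  expect_identical(mask@provenance$method, "plexus_mean_early_10")
})

test_that("the dual mask is the union of the single-timepoint masks", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 4))
  pan <- measureReferencePanel(ph$vol10, ph$vol60,
                               defaultPlacements(ph$spec))
  early <- delineate(ph$vol10, ph$vol60, pan, "plexus_mean_early_10")
  late <- delineate(ph$vol10, ph$vol60, pan, "plexus_late_12")
  dual <- delineate(ph$vol10, ph$vol60, pan, "dual_plexus")
  expect_identical(dual@mask, early@mask | late@mask)
  expect_true(all(dual@mask[early@mask]))
  expect_true(all(dual@mask[late@mask]))

  # restriction intersects with the supplied mask
  restricted <- delineate(ph$vol10, ph$vol60, pan,
                          delineationRule("dual_plexus",
                                          restrictTo = ph$flair))
  expect_identical(restricted@mask, dual@mask & ph$flair)
  expect_true(restricted@provenance$restricted)
})

test_that("lowering a threshold never shrinks a mask", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 11))
  bg <- 1.0
  m1 <- tbrMap(ph$vol10, bg) > 1.2
  m2 <- tbrMap(ph$vol10, bg) > 1.0
  expect_true(all(m2[m1]))
})

test_that("mask metrics measure overlap and volume", {
  a <- array(FALSE, c(10, 10, 10))
  a[1:4, 1:4, 1:4] <- TRUE
  expect_equal(maskMetrics(a, a, voxelSize = 2)$dice, 1)
  b <- array(FALSE, c(10, 10, 10))
  b[6:9, 6:9, 6:9] <- TRUE
  expect_equal(maskMetrics(a, b, voxelSize = 2)$dice, 0)
  # A = half of B: Dice 2/3
  half <- array(FALSE, c(10, 10, 10))
  half[1:4, 1:4, 1:2] <- TRUE
  expect_equal(maskMetrics(half, a, voxelSize = 2)$dice, 2 / 3)
  m <- maskMetrics(a, half, voxelSize = 2)
  expect_equal(m$volumeAMl, 64 * 8 / 1000)
  expect_equal(m$volumeBMl, 32 * 8 / 1000)
  expect_equal(m$aMinusBMl, 32 * 8 / 1000)
  expect_error(maskMetrics(a, array(FALSE, c(5, 5, 5)), voxelSize = 2),
               "grid mismatch")
})

test_that("CE+2cm comparator dilates the CE mask isotropically", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 2))
  vs <- voxelSize(ph$vol10)
  ce2 <- dilateMask(ph$ce, 20, voxelSize = vs)
  expect_true(all(ce2[ph$ce]))
  # grows by roughly the analytic shell of a 20 mm margin
  expect_gt(sum(ce2), sum(ph$ce) * 3)
})
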