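test_that("sphere discretization approximates the nominal volume", {
  vol <- uniformVolume(1, dims = c(30, 30, 30), voxelSize = 1)
  vox <- voxelsInVOI(vol, voiSpec("thalamus", c(15, 15, 15), 1))
  expect_lt(abs(nrow(vox) - 1000) / 1000, 0.15)
  # finer voxels shrink the discretization error
  volFine <- uniformVolume(1, dims = c(60, 60, 60), voxelSize = 0.5)
  voxFine <- voxelsInVOI(volFine, voiSpec("thalamus", c(15, 15, 15), 1))
  errCoarse <- abs(nrow(vox) * 1 - 1000) / 1000
  errFine <- abs(nrow(voxFine) * 0.5^3 - 1000) / 1000
  expect_lt(errFine, errCoarse)
  # determinism
  expect_identical(vox, voxelsInVOI(vol, voiSpec("thalamus", c(15, 15, 15), 1)))
})

test_that("degenerate and out-of-bounds VOIs error", {
  vol <- uniformVolume(1, dims = c(10, 10, 10), voxelSize = 1)
  # implied radius under half a voxel, centered between voxel centers
  tiny <- new("VOISpec", structure = "custom", shape = "sphere",
              center = c(5, 5, 5), volumeCm3 = 4e-4, planeAxis = 3L)
  expect_error(voxelsInVOI(vol, tiny), "smaller than one voxel")
  expect_error(
    voxelsInVOI(vol, voiSpec("sinus", c(1, 5, 5), 0.5)),
    "out of bounds")
  # nominal volumes outside the allowed per-structure range are rejected
  expect_error(voiSpec("brain", c(5, 5, 5), 2), "must lie in")
  expect_warning(voiSpec("artery", c(5, 5, 5), 0.004), "resolution")
})

test_that("voiStatistic computes means and maxima over member voxels", {
  vol <- uniformVolume(0.77, dims = c(30, 30, 30), voxelSize = 1)
  voi <- voiSpec("thalamus", c(15, 15, 15), 0.75)
  expect_equal(voiStatistic(vol, voi, "mean"), 0.77)
  expect_equal(voiStatistic(vol, voi, "max"), 0.77)

  vals <- array(1, dim = c(30, 30, 30))
  vals[15, 15, 15] <- 2
  volHot <- SUVVolume(vals, voxelSize = 1)
  expect_equal(voiStatistic(volHot, voi, "max"), 2)
  expect_gte(voiStatistic(volHot, voi, "max"),
             voiStatistic(volHot, voi, "mean"))

  # checkerboard 0/2: mean equals the exact included-voxel average
  cb <- array(0, dim = c(30, 30, 30))
  idx <- which(arrayInd(seq_along(cb), dim(cb)) %*% c(1, 1, 1) %% 2 == 0)
  cb[idx] <- 2
  volCb <- SUVVolume(cb, voxelSize = 1)
  vox <- voxelsInVOI(volCb, voi)
  expected <- mean(cb[vox])
  expect_equal(voiStatistic(volCb, voi, "mean"), expected)
  expect_lt(abs(expected - 1), 2 / nrow(vox) + 0.01)
})

test_that("pointSUV reads the nearest voxel with a lower-index tie rule", {
  vals <- array(seq_len(8), dim = c(2, 2, 2))
  vol <- SUVVolume(vals, voxelSize = 1)
  # exact voxel centers
  expect_equal(pointSUV(vol, c(0.5, 0.5, 0.5)), vals[1, 1, 1])
  expect_equal(pointSUV(vol, c(1.5, 0.5, 0.5)), vals[2, 1, 1])
  # face midpoint x = 1: tie between voxels 1 and 2, lower index wins
  expect_equal(pointSUV(vol, c(1, 0.5, 0.5)), vals[1, 1, 1])
  expect_error(pointSUV(vol, c(3, 0.5, 0.5)), "outside")
})

test_that("reference panels measured on phantoms match the truth", {
  ph <- generatePhantom(defaultPhantomSpec(noiseSd = 0, seed = 1),
                        medianUptakeModel())
  pan <- measureReferencePanel(ph$vol10, ph$vol60,
                               defaultPlacements(ph$spec))
  expect_equal(panelValue(pan, "plexus", "max", "T10"), 1.07)
  expect_equal(panelValue(pan, "plexus", "max", "T60"), 0.91)
  expect_equal(panelValue(pan, "brain", "mean", "T10"), 0.60)
  expect_equal(panelValue(pan, "thalamus", "mean", "T10"), 0.77)
  expect_equal(panelValue(pan, "sinus", "max", "T60"), 1.45)

  # identical volumes at both timepoints give a symmetric panel
  panSym <- measureReferencePanel(ph$vol10, ph$vol10,
                                  defaultPlacements(ph$spec))
  v <- panSym@values
  for (e in grep("_10$", names(v), value = TRUE))
    expect_equal(unname(v[e]), unname(v[sub("_10$", "_60", e)]))

  # max >= mean on a noisy phantom
  phN <- generatePhantom(defaultPhantomSpec(seed = 3))
  panN <- measureReferencePanel(phN$vol10, phN$vol60,
                                defaultPlacements(phN$spec))
  for (s in c("brain", "thalamus", "plexus")) {
    for (tp in c("T10", "T60")) {
      expect_gte(panelValue(panN, s, "max", tp),
                 panelValue(panN, s, "mean", tp))
    }
  }

  expect_error(
    measureReferencePanel(ph$vol10, ph$vol60,
                          defaultPlacements(ph$spec)[c("brain", "plexus")]),
    "thalamus")
})

test_that("dilation is Euclidean, monotone and contains its input", {
  m <- array(FALSE, c(31, 31, 31))
  m[16, 16, 16] <- TRUE
  expect_identical(dilateMask(m, 0, voxelSize = 2), m)
  expect_error(dilateMask(m, -1, voxelSize = 2), "non-negative")

  # single voxel dilated by 20 mm at 2 mm voxels: near-analytic ball
  d <- dilateMask(m, 20, voxelSize = 2)
  analytic <- (4 / 3) * pi * 10^3  # in voxel volumes
  expect_lt(abs(sum(d) - analytic) / analytic, 0.10)
  expect_true(all(d[m]))

  # monotonicity: A subset of B implies dilate(A) subset of dilate(B)
  set.seed(4)
  B <- array(runif(27e3) < 0.02, c(30, 30, 30))
  A <- B & (array(runif(27e3), c(30, 30, 30)) < 0.5)
  dA <- dilateMask(A, 6, voxelSize = 2)
  dB <- dilateMask(B, 6, voxelSize = 2)
  expect_true(all(dB[dA]))
  expect_true(all(dA[A]))
})
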