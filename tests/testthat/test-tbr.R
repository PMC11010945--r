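test_that("computeTBR is a guarded ratio", {
  expect_equal(computeTBR(1.5, 1.5), 1.0)
  # astrogliosis early median over brain early median
  expect_equal(computeTBR(1.04, 0.60), 1.04 / 0.60)
  expect_error(computeTBR(1, 0), "invalid background")
  expect_error(computeTBR(1, -2), "invalid background")
})

test_that("buildFeatureRow populates every feature and the module", {
  pan <- flatPanel(1)
  row <- buildFeatureRow(list(suv10 = 2.0, suv60 = 1.2), pan)
  expect_true(all(fetquant:::.FEATURE_COLS %in% names(row)))
  expect_equal(row$tbr_plexus_10, 2.0)
  expect_equal(row$tbr_plexus_60, 1.2)
  expect_equal(row$module, 0.8)

  # equal SUVs against a symmetric panel: module vanishes
  rowSym <- buildFeatureRow(list(suv10 = 1.4, suv60 = 1.4), pan)
  expect_equal(rowSym$module, 0)

  # module is symmetric in the two timepoints
  a <- buildFeatureRow(list(suv10 = 2.4, suv60 = 1.1), pan)$module
  b <- buildFeatureRow(list(suv10 = 1.1, suv60 = 2.4), pan)$module
  expect_equal(a, b)

  badVals <- pan@values
  badVals["sinus_max_60"] <- NA
  badPan <- ReferencePanel(badVals)
  expect_error(buildFeatureRow(list(suv10 = 1, suv60 = 1), badPan),
               "sinus")
})

test_that("featureMatrix applies complete-case filtering", {
  tab <- generateSampleTable(sampleTableSpec(nSamples = 284, seed = 31))
  pans <- generateReferencePanels(23, seed = 32)
  # knock out a SUV in 22 rows, mirroring the published missing-data count
  withNA <- tab
  withNA$suv10[seq_len(11)] <- NA
  withNA$suv60[284 - seq_len(11) + 1] <- NA
  fm <- featureMatrix(withNA, pans, completeCase = TRUE)
  expect_identical(nrow(fm), 262L)
  expect_identical(attr(fm, "nDropped"), 22L)

  # without missing data the row count is preserved
  fmFull <- featureMatrix(tab, pans)
  expect_identical(nrow(fmFull), 284L)
  expect_identical(attr(fmFull, "nDropped"), 0L)

  # column set independent of row order
  shuffled <- tab[sample.int(nrow(tab)), ]
  expect_identical(names(featureMatrix(shuffled, pans)), names(fmFull))

  allNA <- tab
  allNA$suv10 <- NA
  expect_error(featureMatrix(allNA, pans), "no complete cases")
  expect_error(featureMatrix(tab[0, ], pans), "non-empty")
})

test_that("TBR features are invariant to a common SUV rescaling", {
  tab <- generateSampleTable(sampleTableSpec(nSamples = 40, seed = 8))
  pans <- generateReferencePanels(23, seed = 9)
  fm <- featureMatrix(tab, pans)

  scaled <- tab
  scaled$suv10 <- scaled$suv10 * 2.5
  scaled$suv60 <- scaled$suv60 * 2.5
  pansScaled <- pans
  for (col in setdiff(names(pans), "patient_id"))
    pansScaled[[col]] <- pans[[col]] * 2.5
  fmScaled <- featureMatrix(scaled, pansScaled)
  for (col in fetquant:::.FEATURE_COLS)
    expect_equal(fmScaled[[col]], fm[[col]])
})

test_that("noise-free phantom features equal hand-computed median ratios", {
  ph <- generatePhantom(defaultPhantomSpec(noiseSd = 0, seed = 1),
                        medianUptakeModel())
  pan <- measureReferencePanel(ph$vol10, ph$vol60,
                               defaultPlacements(ph$spec))
  # a coordinate deep inside the G3 core
  ctr <- ph$spec@tumorCenter
  s10 <- pointSUV(ph$vol10, ctr)
  s60 <- pointSUV(ph$vol60, ctr)
  expect_equal(s10, 1.96)
  row <- buildFeatureRow(list(suv10 = s10, suv60 = s60), pan)
  expect_equal(row$tbr_brain_10, 1.96 / 0.60)
  expect_equal(row$tbr_plexus_10, 1.96 / 1.07)
  expect_equal(row$tbr_plexus_60, 2.18 / 0.91)
  expect_equal(row$module, abs(1.96 / 1.07 - 2.18 / 0.91))
})
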