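# fetquant

Dual-timepoint FET-PET quantification of glioma infiltration.

`fetquant` is an R package for neuro-oncology imaging scientists working
on amino-acid PET delineation of diffuse gliomas. At the infiltration
border, reactive astrogliosis and grade-2 tumor show overlapping
O-(2-[18F]fluoroethyl)-L-tyrosine (FET) uptake, and the conventional
rule — tumor where SUV exceeds 1.6 × the contralateral-brain VOI mean on
the standard 40–60 min acquisition — is sensitive but unspecific there.
The package implements a quantification protocol built on two ideas:
dual-timepoint acquisition (early ≈ 10 min and standard ≈ 60 min after
injection) and target-to-background ratios

&nbsp;&nbsp;&nbsp;&nbsp;TBR = SUV_target / SUV_background

against reference structures beyond the brain — most importantly the
choroid plexus, whose uptake falls over time like high-grade tumor while
astrogliosis, grade-2 tumor, brain and thalamus rise. On top of the
feature layer it provides the published decision rules (single
thresholds, the dual plexus rule TBR₁₀ > 1.0 ∨ TBR₆₀ > 1.2, the
two-branch plexus/module decision tree, thalamus rules), a CART trainer
with exhaustive Gini split search and cross-validation cost reporting,
ROC diagnostics (Mann–Whitney AUC, DeLong confidence intervals,
Youden-optimal cutoffs, paired curve comparison), and voxelwise
tumor-extent delineation with Dice/volume mask comparison. Because the
underlying patient data are not public, a first-class synthetic-data
module generates biopsy-sample tables and 3-D dual-timepoint phantoms
calibrated to the published uptake summaries, so the entire pipeline is
testable offline.

## Worked example

```r
library(fetquant)

## a synthetic cohort calibrated to the published summaries
tab    <- generateSampleTable(sampleTableSpec(nSamples = 284, seed = 11))
panels <- generateReferencePanels(23, seed = 12)
feats  <- featureMatrix(tab, panels)
truth  <- feats$histology %in% c("G2", "G3", "G4")

## how well does the early plexus-referenced TBR separate tumor from
## astrogliosis in this cohort?
rocAnalysis(feats$tbr_plexus_roimean_10, truth)
#> ROCResult: AUC 0.687 (95% CI 0.610-0.764, delong), 229 pos / 55 neg
#>   Youden-optimal cutoff: 1.08

## the standard brain rule on the same samples
m <- confusionMetrics(truth,
  applyThresholdRule(feats, thresholdRule("tbr_brain_60", 1.6)) == "tumor")
sprintf("brain 1.6 rule: sens %.2f spec %.2f", m$sensitivity, m$specificity)
#> "brain 1.6 rule: sens 0.87 spec 0.22"

## the published decision tree over (late plexus TBR, module)
publishedTreeClassify(c(2.0, 1.5, 0.9), c(1.5, 1.0, 5.0))
#> [1] "tumor"        "tumor"        "astrogliosis"

## voxelwise delineation on a synthetic dual-timepoint phantom
ph   <- generatePhantom(defaultPhantomSpec(seed = 11))
pan  <- measureReferencePanel(ph$vol10, ph$vol60, defaultPlacements(ph$spec))
mask <- delineate(ph$vol10, ph$vol60, pan, "plexus_mean_early_10")
volumeMl(mask)
#> [1] 24.008
maskMetrics(mask, phantomTumorMask(ph), voxelSize = voxelSize(ph$vol10))$dice
#> [1] 0.544
```

The ROC result reads as: across 229 tumor and 55 astrogliosis samples,
ranking by the early plexus-referenced TBR separates the classes with
AUC 0.69, and the cutoff maximizing Youden's J lands at 1.08 — close to
the published operating point of 1.0. The delineation mask is the raw
`TBR > 1.0` contour of the early volume against the measured plexus ROI
mean; its Dice of 0.54 is against the phantom's true G2∪G3∪G4
compartment.

An end-to-end run (simulate → extract → features → evaluate → delineate
→ contingency, with CSV/JSON/NIfTI outputs) is one call:

```r
report <- runPipeline(defaultRunConfig(seed = 101, outDir = "run1"))
```

`verifyFixtures()` checks the packaged transcriptions of the published
summary tables (checksums, row/column sums, percentage and
predictive-value consistency).

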