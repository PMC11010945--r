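---
title: "Methods: dual-timepoint FET-PET quantification at the glioma border"
author: "fetquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-timepoint FET-PET quantification at the glioma border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetquant)
```

## The problem

Diffuse gliomas infiltrate far beyond the contrast-enhancing mass, and at
the infiltration border the main confounder for amino-acid PET is
reactive astrogliosis: non-neoplastic glial tissue whose
O-(2-[18F]fluoroethyl)-L-tyrosine (FET) uptake overlaps that of grade-2
tumor. The conventional semiquantitative rule — tumor where uptake
exceeds 1.6 times the mean of a contralateral-brain volume of interest on
the standard (40--60 min post-injection) acquisition — is sensitive but
unspecific at this border. `fetquant` implements an analysis protocol
that improves the separation by (i) acquiring at two timepoints (early,
about 10 min after injection, and standard) and (ii) referencing uptake
to structures other than the brain, foremost the choroid plexus, whose
physiologically high uptake *falls* over time like high-grade tumor while
astrogliosis, grade-2 tumor, brain and thalamus *rise*.

The quantities involved are standardized uptake values (SUV; tissue
tracer concentration normalized to injected dose and body weight,
unitless) and target-to-background ratios
$\mathrm{TBR} = \mathrm{SUV}_{target} / \mathrm{SUV}_{background}$, where
the background is the mean or maximum SUV in a sphere VOI or single-plane
circle ROI placed on a reference structure.

## Decision rules

All published rules are implemented as deterministic classifiers over the
per-sample TBR feature row (`buildFeatureRow`, `featureMatrix`):

* **Single thresholds** (`applyThresholdRule`): tumor when the feature
  strictly exceeds the cutoff (e.g. brain-referenced TBR > 1.6; early
  plexus-ROI-mean TBR > 1.0; late plexus TBR > 1.2).
* **Dual plexus rule** (`dualPlexusRule`): tumor when the early plexus
  TBR exceeds 1.0 *or* the late plexus TBR exceeds 1.2. The disjunctive
  reading is a design choice: the published behavior of the dual rule —
  sensitivity up, specificity down relative to the late acquisition
  alone — is only produced by a union.
* **Published tree** (`publishedTreeClassify`): over the late plexus TBR
  $t$ and the dual-timepoint module
  $m = |\mathrm{TBR}^{plexus}_{10} - \mathrm{TBR}^{plexus}_{60}|$, tumor
  iff $(t > 1.77 \wedge m > 1.11) \vee (1.05 < t \le 1.77 \wedge m <
  3.19)$. Boundary conventions (1.77 inclusive in the middle branch,
  1.05 exclusive; the unlabeled region $t \in (1.05, 1.77], m \ge 3.19$
  classified as astrogliosis) follow the stated complement and are
  locked in tests. "Module" is read as the modulus (absolute
  difference) of the two plexus TBRs, computed from the plexus
  *maximum* variant; the ROI-mean variant is also computed in every
  feature row so either convention can be evaluated.
* **Thalamus rules** (`thalamusRule`): within the thalamus — a structure
  of naturally higher uptake — pathological means absolute SUV > 1.0
  (early) / > 1.1 (late), or a ratio to the contralateral thalamus
  ≥ 1.7 (early) / ≥ 1.6 (late). Strict versus inclusive comparisons
  follow the printed symbols.

## CART trainer

`fitCart` re-implements the tree-induction procedure used to derive the
published tree: binary recursive partitioning with exhaustive Gini
split search (all features, all midpoints between adjacent distinct
values; ties resolved toward the earlier feature column, then the lower
threshold), a *direct stop* rule expressed as a minimum node fraction
(default 0.05 of the training rows — the exact proprietary stopping
heuristic of the original software is not public, so the conventional
minimum-node-size reading is used), a maximum depth (default 10), and a
pure-node stop. Each node carries a Fisher exact p-value for class
membership inside versus outside the node; the p-values are descriptive
and never drive split selection. Model adequacy is judged the way the
original analysis describes: the resubstitution misclassification cost
is compared against the V-fold cross-validation cost ± SE (default 10
folds; SE is the standard error of the per-observation 0/1 loss).
Cost-complexity pruning and surrogate splits are intentionally out of
scope.

## ROC diagnostics

`rocAnalysis` computes operating points over the candidate cutoffs
(midpoints between adjacent distinct scores; a sample is positive when
its score exceeds the cutoff), the Mann--Whitney AUC with ties counted
one half, and a 95% confidence interval — DeLong by default, percentile
bootstrap behind a flag as a cross-check. The Youden-optimal cutoff
maximizes $J = \mathrm{sens} + \mathrm{spec} - 1$ over the candidate
set, ties broken toward higher sensitivity and then the lower cutoff.
`compareROCPaired` wraps the paired DeLong test; identical score
vectors return $p = 1$ by convention. `metricsFromRates` converts
published sensitivity/specificity plus class sizes into the implied
PPV/NPV, which is how the package checks the internal consistency of
the published accuracy table (230 tumor vs 54 astrogliosis samples).

## Synthetic data: what is emulated

No raw data accompany the study this package is calibrated to, so the
`synthetic_data` layer generates inputs whose printed summaries it can
reproduce:

* **Marginal SUV distributions.** Each (tissue, timepoint) is modeled by
  a piecewise log-linear quantile function through the printed
  five-number summary (min, lower quartile, median, upper quartile,
  max). This reproduces every printed quantile exactly and cannot leave
  the printed range. A truncated-lognormal family (matched to median
  and IQR via `fitLognormalFromQuantiles`, truncated to the printed
  range) is provided for comparison, but it is not the default: for
  left-skewed rows — the grade-4 early-timepoint row has mean 2.50 <
  median 2.75 — truncation drags the lognormal's median about 13%
  below the printed value, violating the 5% calibration requirement.
* **Dual-timepoint coupling.** The two timepoints of one sample are
  coupled by a Gaussian copula (default correlation 0.8, a deliberately
  strong within-sample kinetic coherence; the source prints no joint
  distribution). Marginals are exact by construction, and the kinetic
  direction — astrogliosis, G2, brain and thalamus rising; plexus,
  sinus and G4 falling — follows from the printed medians.
* **Cohort composition.** Trajectory classes (T1-GAD, PET, PET−, FLAIR)
  and histology given trajectory are drawn from the packaged 284-sample
  contingency table (91/110/11/72 per trajectory; e.g. 38 of 72 FLAIR
  samples astrogliosis).
* **Phantoms.** `generatePhantom` builds a 64 × 64 × 48 grid at 2 mm
  isotropic voxels (the scanner resolution the protocol reports is
  under 4 mm): nested tumor ellipsoids (core of a chosen grade, G2
  shell, astrogliosis shell) inside a FLAIR ellipsoid with a CE subset,
  and spherical reference structures in the contralateral hemisphere.
  Voxel values are drawn in two tiers reflecting what the calibrated
  tables describe: the reference-structure summaries are *per-patient*
  measurements (one value per patient), so each normal structure gets a
  single patient-level value per timepoint, all structures sharing one
  latent quantile so the physiologic within-patient ordering (plexus
  above brain, etc.) always holds; the per-grade summaries describe
  *individual biopsy samples*, so lesional voxels are drawn
  independently per voxel. Additive Gaussian voxel noise (default sd
  0.05 SUV; the source states no voxel-noise model) is applied on top
  and clipped at zero.

What the generator deliberately does **not** emulate: PET physics
(attenuation, scatter, partial-volume, reconstruction), spatial
autocorrelation within lesions, MRI beyond binary FLAIR/CE masks, and —
importantly — any correlation between a patient's lesion uptake and that
patient's background uptake, because only marginal summaries are
printed. Passing calibration tests therefore demonstrate fidelity to
the printed marginals and cell proportions, not to joint, spatial or
patient-level structure of real data.

## Geometry and numerical conventions

* World coordinates are continuous mm with voxel centers at
  $(i - \tfrac12)\,\Delta$ for 1-based index $i$; sphere membership is
  by voxel-center distance with radius $r = (3V/4\pi)^{1/3}$; circles
  are one voxel-plane thick (default axial) with
  $r = \sqrt{V/(\pi\,t)}$.
* Point SUVs read the nearest voxel center, no interpolation; at an
  exact face tie the lower index wins.
* Nominal VOI volumes are constrained per structure (brain sphere
  10--20 cm³, thalamus 0.5--1 cm³, sinus 0.3--0.8 cm³, plexus circle
  0.3--0.6 cm³, artery circle 3--5 mm³); the artery ROI is below
  scanner resolution and is allowed with a warning.
* Mask dilation (`dilateMask`) is exact Euclidean dilation implemented
  by FFT convolution with the discrete ball, so the "CE + 2 cm"
  radiotherapy comparator is the CE mask dilated by 20 mm.
* Delineation masks are raw threshold contours — no connected-component
  filtering or hole-filling — and their background scalars come from
  the reference panel, never from inside the candidate region.
* No partial-volume correction anywhere, matching the protocol.

## Problem sizes

The shipped tests and the acceptance script use 10,000-draw calibration
checks per tissue, 200 random ROC instances (n ≤ 50) against a
brute-force pair-count oracle, 20-table CART split-oracle checks
(n ≤ 200) plus 50 permuted-label cross-validation replicates, and 20
phantom seeds for the delineation comparison; the full suite runs in
well under a minute on one core.

## Known limitations

* Sample SUVs and patient backgrounds are drawn independently, so TBR
  distributions are wider than in real patients (where TBR cancels
  patient-level scale). Consequently the *ordering* results that depend
  on that joint structure — the published superiority of the early
  plexus reference over the brain reference, both as paired AUCs and as
  voxelwise Dice against the phantom's true tumor compartment — do not
  reproduce from marginal calibration alone; the package computes and
  reports both sides of each comparison rather than building the
  expected ordering into the generator.
* The plexus ROI mean has no separate published summary; it is modeled
  with the same distribution as the plexus maximum (the ROI is small),
  making the two variants coincide in synthetic panels (they differ on
  phantoms, where both are measured from voxels).
* The published integer percentages of the cohort table deviate from
  exact half-up rounding in three cells; recomputation allows a
  one-point difference there.
* Which sample count (284 or the 262 complete cases) entered each
  published ROC row is not stated; `featureMatrix(completeCase =)`
  exposes both options.
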