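## Packaged calibration fixtures: plain-text transcriptions of the printed
## summary tables of the biopsy-controlled dual-timepoint FET-PET glioma
## study that this package's defaults are calibrated to (284 stereotactic
## samples from 23 patients; per-grade and astrogliosis SUV distributions,
## reference-structure uptake, trajectory x histology composition, and the
## published decision thresholds).

.fixtureFile <- function(file) {
  system.file("extdata", file, package = "fetquant", mustWork = TRUE)
}

## Pinned checksums so a corrupted transcription is caught at run time.
.FIXTURE_MD5 <- c(
  cohort_counts.csv = "a0e042baa5ae21467257953d7fe235b7",
  reference_structure_suv.csv = "811b63f53e85f5fe0d436cc55b2dbefb",
  grade_suv.csv = "d7eec0d243ac1e76980005c010905214",
  threshold_accuracy.csv = "49bc366443837e11ae42505d8c571873",
  decision_thresholds.json = "df3a15afd0b77c7c8f0716f4200820b9")

#' Cohort composition fixture (trajectory x histology counts)
#'
#' Counts and printed percentages of biopsy samples per histology
#' (astrogliosis, G2, G3, G4) and biopsy-trajectory class (T1-GAD, PET,
#' PET-, FLAIR), for the 284-sample calibration cohort.
#'
#' @return A \code{data.frame} with one row per histology and count /
#'   percent columns per trajectory plus the overall column.
#' @export
cohortCounts <- function() {
  utils::read.csv(.fixtureFile("cohort_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference-structure SUV summary fixture
#'
#' Per-structure SUV distribution summaries (N, mean, median, min, max,
#' quartiles, SD) at the early ("10") and late ("60") timepoints for the
#' background structures: choroid plexus (max ROI), thalamus (mean and
#' max), contralateral brain (mean and max), middle cerebral artery, and
#' venous sinus.
#'
#' @return A \code{data.frame}, one row per (structure, timepoint).
#' @export
referenceStructureTable <- function() {
  tab <- utils::read.csv(.fixtureFile("reference_structure_suv.csv"),
                         stringsAsFactors = FALSE)
  tab$timepoint <- as.character(tab$timepoint)
  tab
}

#' Per-grade sample SUV summary fixture
#'
#' SUV distribution summaries of individual biopsy samples by histology
#' (astrogliosis, G2, G3, G4) at both timepoints.
#'
#' @return A \code{data.frame}, one row per (histology, timepoint).
#' @export
gradeUptakeTable <- function() {
  tab <- utils::read.csv(.fixtureFile("grade_suv.csv"),
                         stringsAsFactors = FALSE)
  tab$timepoint <- as.character(tab$timepoint)
  tab
}

#' Published threshold-accuracy fixture
#'
#' Published cutoffs and operating characteristics (sensitivity,
#' specificity, PPV, NPV, AUC with 95\% CI) of the TBR features against
#' each background structure, at both timepoints.
#'
#' @return A \code{data.frame}, one row per (timepoint, feature).
#' @export
thresholdAccuracyTable <- function() {
  tab <- utils::read.csv(.fixtureFile("threshold_accuracy.csv"),
                         stringsAsFactors = FALSE)
  tab$timepoint <- as.character(tab$timepoint)
  tab
}

#' Published decision thresholds
#'
#' The constants of the published tumor-versus-astrogliosis decision tree
#' (plexus-TBR split points and the dual-timepoint "module" feature
#' bounds), the standard 1.6 x brain threshold, the dual plexus rule
#' cutoffs, and the thalamus absolute/relative thresholds.
#'
#' @return A nested list.
#' @export
decisionThresholds <- function() {
  jsonlite::read_json(.fixtureFile("decision_thresholds.json"),
                      simplifyVector = TRUE)
}

#' Expand the cohort fixture into one row per sample
#'
#' Turns the trajectory x histology count table into a sample-level
#' \code{data.frame} (no SUVs), convenient for contingency summaries.
#'
#' @return A \code{data.frame} with columns \code{trajectory} and
#'   \code{histology}, one row per sample.
#' @export
cohortSamples <- function() {
  counts <- cohortCounts()
  cols <- c(t1gad_n = "T1-GAD", pet_n = "PET", petminus_n = "PET-",
            flair_n = "FLAIR")
  rows <- do.call(rbind, lapply(names(cols), function(cn) {
    do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      n <- counts[[cn]][i]
      if (n == 0) return(NULL)
      data.frame(trajectory = cols[[cn]], histology = counts$histology[i],
                 stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Verify the packaged fixtures
#'
#' Checks the pinned checksums of every packaged fixture file and
#' recomputes the derived quantities of each table: row/column sums and
#' integer percentages of the cohort table, quantile ordering of the SUV
#' summaries, and consistency of the published PPV/NPV with the published
#' sensitivity/specificity and the 230/54 class split (within the slack
#' implied by two-decimal rounding of the printed rates).
#'
#' @return A \code{data.frame} with columns \code{check}, \code{pass} and
#'   \code{detail}; an error is raised if a fixture checksum mismatches.
#' @examples
#' chk <- verifyFixtures()
#' all(chk$pass)
#' @export
verifyFixtures <- function() {
  files <- names(.FIXTURE_MD5)
  sums <- tools::md5sum(vapply(files, .fixtureFile, ""))
  names(sums) <- files
  bad <- files[sums != .FIXTURE_MD5[files]]
  if (length(bad))
    stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))

  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  halfUp <- function(x) floor(x + 0.5)

  counts <- cohortCounts()
  trajN <- counts[c("t1gad_n", "pet_n", "petminus_n", "flair_n")]
  add("cohort: trajectory counts sum to overall column",
      all(rowSums(trajN) == counts$overall_n))
  add("cohort: overall total is 284", sum(counts$overall_n) == 284,
      sprintf("total = %d", sum(counts$overall_n)))
  tumor <- sum(counts$overall_n[counts$histology %in% .TUMOR_TISSUES])
  add("cohort: tumor samples total 230", tumor == 230,
      sprintf("tumor = %d", tumor))
  ## the published table's integer percentages deviate from exact
  ## half-up rounding by up to one point in three cells; allow that
  pctOK <- TRUE
  for (col in c("overall", "t1gad", "pet", "petminus", "flair")) {
    n <- counts[[paste0(col, "_n")]]
    printed <- counts[[paste0(col, "_pct")]]
    recomputed <- halfUp(100 * n / sum(n))
    pctOK <- pctOK && all(abs(recomputed - printed) <= 1)
  }
  add("cohort: printed percentages match recomputation within 1 point",
      pctOK)

  for (tabName in c("reference_structure", "grade")) {
    tab <- if (tabName == "reference_structure") referenceStructureTable()
           else gradeUptakeTable()
    ok <- all(tab$min <= tab$lower_q & tab$lower_q <= tab$median &
              tab$median <= tab$upper_q & tab$upper_q <= tab$max)
    add(sprintf("%s: quantiles ordered min <= LQ <= median <= UQ <= max",
                tabName), ok)
    add(sprintf("%s: all SUVs positive", tabName), all(tab$min > 0))
  }

  acc <- thresholdAccuracyTable()
  add("accuracy: AUC inside its CI",
      all(acc$ci_low <= acc$auc & acc$auc <= acc$ci_high))
  dec <- decisionThresholds()
  nPos <- dec$n_tumor
  nNeg <- dec$n_astrogliosis
  pvOK <- TRUE
  worst <- 0
  for (i in seq_len(nrow(acc))) {
    dev <- max(
      .rateIntervalDistance(acc$ppv[i], acc$sensitivity[i],
                            acc$specificity[i], nPos, nNeg, "ppv"),
      .rateIntervalDistance(acc$npv[i], acc$sensitivity[i],
                            acc$specificity[i], nPos, nNeg, "npv"))
    worst <- max(worst, dev)
    pvOK <- pvOK && dev <= 0.02
  }
  add("accuracy: printed PPV/NPV consistent with printed rates and 230/54",
      pvOK, sprintf("max deviation %.4f", worst))

  tree <- dec$published_tree
  add("decision tree: split points ordered",
      tree$plexus60_lo < tree$plexus60_hi)

  do.call(rbind, checks)
}

## Distance from a printed predictive value to the interval of values
## achievable when the printed sensitivity/specificity are perturbed
## within their two-decimal rounding half-width (+-0.005).
.rateIntervalDistance <- function(printed, sens, spec, nPos, nNeg, which) {
  eps <- 0.005
  sensRange <- pmin(pmax(c(sens - eps, sens + eps), 0), 1)
  specRange <- pmin(pmax(c(spec - eps, spec + eps), 0), 1)
  vals <- vapply(seq_len(4), function(k) {
    s <- sensRange[((k - 1) %/% 2) + 1]
    p <- specRange[((k - 1) %% 2) + 1]
    m <- metricsFromRates(s, p, nPos, nNeg)
    if (which == "ppv") m$ppv else m$npv
  }, 0)
  lo <- min(vals)
  hi <- max(vals)
  if (printed < lo) lo - printed else if (printed > hi) printed - hi else 0
}
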