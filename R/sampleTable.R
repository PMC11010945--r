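#' SampleTableSpec: design of a synthetic biopsy-sample table
#'
#' Number of samples, marginal mix of biopsy-trajectory classes, and the
#' conditional histology distribution given trajectory from which a
#' synthetic sample table is drawn.
#'
#' @slot nSamples number of samples to generate.
#' @slot trajectoryMix named probability vector over the four trajectory
#'   classes (T1-GAD, PET, PET-, FLAIR).
#' @slot histologyGivenTrajectory 4 x 4 matrix of conditional
#'   probabilities, rows = trajectories, columns = histologies
#'   (astrogliosis, G2, G3, G4); each row sums to 1.
#' @slot seed integer seed (NA for none).
#' @exportClass SampleTableSpec
setClass("SampleTableSpec",
         representation(nSamples = "integer",
                        trajectoryMix = "numeric",
                        histologyGivenTrajectory = "matrix",
                        seed = "numeric"))

setValidity("SampleTableSpec", function(object) {
  if (object@nSamples < 0)
    return("'nSamples' must be non-negative")
  mix <- object@trajectoryMix
  if (!identical(names(mix), .TRAJECTORIES))
    return(paste("'trajectoryMix' must be named",
                 paste(.TRAJECTORIES, collapse = ", ")))
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    return("'trajectoryMix' must be a probability vector summing to 1")
  cond <- object@histologyGivenTrajectory
  if (!identical(rownames(cond), .TRAJECTORIES) ||
      !identical(colnames(cond), .HISTOLOGY))
    return("'histologyGivenTrajectory' must have trajectory rows and histology columns")
  if (any(cond < 0) || any(abs(rowSums(cond) - 1) > 1e-9))
    return("each conditional probability row must sum to 1")
  TRUE
})

setMethod("show", "SampleTableSpec", function(object) {
  cat(sprintf("SampleTableSpec: n = %d, seed = %s\n", object@nSamples,
              if (is.na(object@seed)) "none" else object@seed))
  cat("  trajectory mix:",
      paste(sprintf("%s %.3f", names(object@trajectoryMix),
                    object@trajectoryMix), collapse = ", "), "\n")
})

#' Construct a SampleTableSpec
#'
#' The default trajectory mix and conditional histology table are the cell
#' proportions of the packaged 284-sample cohort fixture (91 T1-GAD / 110
#' PET / 11 PET- / 72 FLAIR; e.g. 38 of 72 FLAIR samples are
#' astrogliosis).
#'
#' @param nSamples number of samples (default 284, the calibration cohort
#'   size).
#' @param seed optional integer seed for reproducible generation.
#' @param trajectoryMix optional named probability vector over
#'   trajectories; defaults to the fixture column proportions.
#' @param histologyGivenTrajectory optional 4 x 4 conditional probability
#'   matrix; defaults to the fixture cell proportions.
#' @return A \linkS4class{SampleTableSpec}.
#' @examples
#' sampleTableSpec(nSamples = 100, seed = 1)
#' @export
sampleTableSpec <- function(nSamples = 284, seed = NULL,
                            trajectoryMix = NULL,
                            histologyGivenTrajectory = NULL) {
  counts <- cohortCounts()
  cnt <- t(as.matrix(counts[c("t1gad_n", "pet_n", "petminus_n", "flair_n")]))
  dimnames(cnt) <- list(.TRAJECTORIES, counts$histology)
  cnt <- cnt[, .HISTOLOGY, drop = FALSE]
  if (is.null(trajectoryMix)) {
    trajectoryMix <- rowSums(cnt) / sum(cnt)
  }
  if (is.null(histologyGivenTrajectory)) {
    histologyGivenTrajectory <- cnt / rowSums(cnt)
  }
  new("SampleTableSpec", nSamples = as.integer(nSamples),
      trajectoryMix = trajectoryMix,
      histologyGivenTrajectory = histologyGivenTrajectory,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Generate a synthetic biopsy-sample table
#'
#' Draws a table of stereotactic biopsy samples: each sample first draws a
#' trajectory class from the marginal mix, then a histology from the
#' conditional table, then a coupled (SUV10, SUV60) pair from the
#' histology's calibrated uptake distribution. Identical seeds give
#' identical tables.
#'
#' @param spec a \linkS4class{SampleTableSpec}.
#' @param model an \linkS4class{UptakeModel}; default
#'   \code{\link{defaultUptakeModel}()}.
#' @param nPatients number of synthetic patients the samples are spread
#'   over (default 23).
#' @return A \code{data.frame} with columns \code{patient_id},
#'   \code{trajectory}, \code{histology}, \code{suv10}, \code{suv60}.
#' @examples
#' head(generateSampleTable(sampleTableSpec(nSamples = 20, seed = 1)))
#' @export
generateSampleTable <- function(spec, model = defaultUptakeModel(),
                                nPatients = 23) {
  stopifnot(is(spec, "SampleTableSpec"))
  validObject(spec)
  n <- spec@nSamples
  emptyTable <- data.frame(patient_id = character(0),
                           trajectory = character(0),
                           histology = character(0),
                           suv10 = numeric(0), suv60 = numeric(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) return(emptyTable)
  draw <- function() {
    trajectory <- sample(.TRAJECTORIES, n, replace = TRUE,
                         prob = spec@trajectoryMix)
    histology <- character(n)
    for (tr in .TRAJECTORIES) {
      idx <- which(trajectory == tr)
      if (length(idx))
        histology[idx] <- sample(.HISTOLOGY, length(idx), replace = TRUE,
                                 prob = spec@histologyGivenTrajectory[tr, ])
    }
    patient <- sprintf("P%02d", sample.int(nPatients, n, replace = TRUE))
    suv10 <- numeric(n)
    suv60 <- numeric(n)
    for (h in .HISTOLOGY) {
      idx <- which(histology == h)
      if (length(idx)) {
        draws <- sampleUptake(model, h, length(idx))
        suv10[idx] <- draws$suv10
        suv60[idx] <- draws$suv60
      }
    }
    data.frame(patient_id = patient, trajectory = trajectory,
               histology = histology, suv10 = suv10, suv60 = suv60,
               stringsAsFactors = FALSE)
  }
  if (is.na(spec@seed)) draw() else withr::with_seed(spec@seed, draw())
}

## Reference-structure draw design: one latent uniform per structure per
## patient, shared between the mean and max variants and both timepoints,
## so that max >= mean holds by construction (the max-variant quantile
## curves dominate the mean-variant curves pointwise) and a patient's
## kinetics are internally consistent. The plexus ROI mean is modeled with
## the same printed (max-ROI) distribution: the plexus ROI is small and no
## separate mean summary is published.
#' Generate synthetic per-patient reference panels
#'
#' Draws per-patient background measurements (brain mean/max, thalamus
#' mean/max, plexus mean/max, artery max, sinus max, at both timepoints)
#' from the calibrated reference-structure distributions.
#'
#' @param nPatients number of patients (default 23).
#' @param seed optional integer seed.
#' @param family sampling family, as in \code{\link{defaultUptakeModel}}.
#' @return A \code{data.frame} with \code{patient_id} and the 16 panel
#'   columns (\code{brain_mean_10}, ..., \code{sinus_max_60}).
#' @examples
#' generateReferencePanels(3, seed = 1)
#' @export
generateReferencePanels <- function(nPatients = 23, seed = NULL,
                                    family = c("quantile", "lognormal")) {
  family <- match.arg(family)
  stopifnot(nPatients >= 1)
  ref <- referenceStructureTable()
  rowFor <- function(structure, tp) {
    row <- ref[ref$structure == structure & ref$timepoint == tp, ]
    if (nrow(row) != 1L)
      stop(sprintf("no reference summary for '%s' at %s", structure, tp))
    row
  }
  ## panel column -> source summary row
  sources <- list(
    brain_mean = "brain", brain_max = "brain_max",
    thalamus_mean = "thalamus", thalamus_max = "thalamus_max",
    plexus_mean = "plexus", plexus_max = "plexus",
    artery_max = "artery", sinus_max = "sinus")
  latentOf <- c(brain_mean = "brain", brain_max = "brain",
                thalamus_mean = "thalamus", thalamus_max = "thalamus",
                plexus_mean = "plexus", plexus_max = "plexus",
                artery_max = "artery", sinus_max = "sinus")
  draw <- function() {
    u <- lapply(stats::setNames(nm = unique(latentOf)),
                function(s) stats::runif(nPatients))
    out <- data.frame(patient_id = sprintf("P%02d", seq_len(nPatients)),
                      stringsAsFactors = FALSE)
    for (entry in names(sources)) {
      for (tp in c("10", "60")) {
        row <- rowFor(sources[[entry]], tp)
        out[[paste(entry, tp, sep = "_")]] <-
          .suvQuantile(u[[latentOf[[entry]]]], row, family)
      }
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Build a ReferencePanel from a one-row data.frame or named vector
#'
#' @param x a one-row \code{data.frame} (e.g. from
#'   \code{\link{generateReferencePanels}}) or a named numeric vector with
#'   the 16 panel entries; an optional \code{patient_id} field is used as
#'   the identifier.
#' @return A \linkS4class{ReferencePanel}.
#' @export
asReferencePanel <- function(x) {
  if (is(x, "ReferencePanel")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    id <- if ("patient_id" %in% names(x)) x$patient_id else "P01"
    vals <- unlist(x[setdiff(names(x), "patient_id")])
    return(ReferencePanel(vals, patientId = id))
  }
  ReferencePanel(x)
}
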