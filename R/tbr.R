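## Feature columns of the per-sample TBR table, in fixed order. The
## "plexus" variant divides by the plexus maximum, the "plexus_roimean"
## variant by the plexus ROI mean; "module" is the absolute difference of
## the (max-variant) plexus TBRs between the two timepoints.
.FEATURE_COLS <- c(
  "tbr_brain_10", "tbr_brain_60",
  "tbr_brain_max_10", "tbr_brain_max_60",
  "tbr_plexus_10", "tbr_plexus_60",
  "tbr_plexus_roimean_10", "tbr_plexus_roimean_60",
  "tbr_thalamus_10", "tbr_thalamus_60",
  "tbr_thalamus_max_10", "tbr_thalamus_max_60",
  "tbr_artery_10", "tbr_artery_60",
  "tbr_sinus_10", "tbr_sinus_60",
  "module")

## feature column -> panel entry that supplies the background
.FEATURE_BACKGROUND <- c(
  tbr_brain_10 = "brain_mean_10", tbr_brain_60 = "brain_mean_60",
  tbr_brain_max_10 = "brain_max_10", tbr_brain_max_60 = "brain_max_60",
  tbr_plexus_10 = "plexus_max_10", tbr_plexus_60 = "plexus_max_60",
  tbr_plexus_roimean_10 = "plexus_mean_10",
  tbr_plexus_roimean_60 = "plexus_mean_60",
  tbr_thalamus_10 = "thalamus_mean_10", tbr_thalamus_60 = "thalamus_mean_60",
  tbr_thalamus_max_10 = "thalamus_max_10",
  tbr_thalamus_max_60 = "thalamus_max_60",
  tbr_artery_10 = "artery_max_10", tbr_artery_60 = "artery_max_60",
  tbr_sinus_10 = "sinus_max_10", tbr_sinus_60 = "sinus_max_60")

#' Target-to-background ratio
#'
#' @param target target SUV (point or regional).
#' @param background reference-structure SUV; must be positive.
#' @return \code{target / background}.
#' @examples
#' computeTBR(1.04, 0.60)
#' @export
computeTBR <- function(target, background) {
  if (any(!is.finite(background)) || any(background <= 0))
    stop("invalid background")
  target / background
}

#' Build the TBR feature row for one biopsy sample
#'
#' Computes every target-to-background ratio of the per-sample feature
#' table (brain mean/max, plexus max and ROI mean, thalamus mean/max,
#' artery max, sinus max, at both timepoints) plus the dual-timepoint
#' \code{module} feature, the absolute difference between the early and
#' late plexus (max-variant) TBR.
#'
#' @param sample a list or one-row \code{data.frame} with \code{suv10} and
#'   \code{suv60} (optionally \code{patient_id}, \code{trajectory},
#'   \code{histology}, carried through).
#' @param panel a \linkS4class{ReferencePanel} (or coercible via
#'   \code{\link{asReferencePanel}}).
#' @return A one-row \code{data.frame} with the 17 feature columns,
#'   prefixed by any identifying columns present in \code{sample}.
#' @examples
#' panel <- asReferencePanel(generateReferencePanels(1, seed = 1))
#' buildFeatureRow(list(suv10 = 2.0, suv60 = 1.5), panel)
#' @export
buildFeatureRow <- function(sample, panel) {
  panel <- asReferencePanel(panel)
  vals <- panel@values
  missing <- names(vals)[is.na(vals)]
  if (length(missing))
    stop("missing reference measurement: ", paste(missing, collapse = ", "))
  suv <- c("10" = sample$suv10, "60" = sample$suv60)
  if (any(!is.finite(suv)) || any(suv <= 0))
    stop("sample SUVs must be positive")
  out <- list()
  for (col in setdiff(.FEATURE_COLS, "module")) {
    tp <- sub(".*_(10|60)$", "\\1", col)
    out[[col]] <- computeTBR(suv[[tp]], vals[[.FEATURE_BACKGROUND[[col]]]])
  }
  out$module <- abs(out$tbr_plexus_10 - out$tbr_plexus_60)
  meta <- intersect(c("patient_id", "trajectory", "histology",
                      "suv10", "suv60"), names(sample))
  cbind(as.data.frame(sample[meta], stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Feature matrix for a table of biopsy samples
#'
#' Joins each sample to its patient's reference panel and computes the
#' full TBR feature row. With \code{completeCase = TRUE} (the default,
#' matching complete-case analysis), rows with any missing SUV or panel
#' background are dropped and the dropped count is reported in the
#' \code{"nDropped"} attribute.
#'
#' @param samples \code{data.frame} with columns \code{patient_id},
#'   \code{suv10}, \code{suv60} (plus any identifying columns).
#' @param panels a \code{data.frame} of panels keyed by \code{patient_id}
#'   (e.g. from \code{\link{generateReferencePanels}}), or a named list of
#'   \linkS4class{ReferencePanel}s.
#' @param completeCase drop rows with missing values (default TRUE).
#' @return A \code{data.frame}, one row per retained sample, with the
#'   identifying columns followed by the 17 feature columns; attribute
#'   \code{nDropped} counts removed rows.
#' @export
featureMatrix <- function(samples, panels, completeCase = TRUE) {
  if (!is.data.frame(samples) || nrow(samples) == 0L)
    stop("'samples' must be a non-empty data.frame")
  if (is.list(panels) && !is.data.frame(panels)) {
    panels <- do.call(rbind, lapply(panels, as.data.frame))
  }
  stopifnot(is.data.frame(panels), "patient_id" %in% names(panels))
  idx <- match(samples$patient_id, panels$patient_id)
  if (any(is.na(idx)))
    stop("no reference panel for patient: ",
         paste(unique(samples$patient_id[is.na(idx)]), collapse = ", "))
  pan <- panels[idx, , drop = FALSE]

  out <- samples[intersect(c("patient_id", "trajectory", "histology",
                             "suv10", "suv60"), names(samples))]
  for (col in setdiff(.FEATURE_COLS, "module")) {
    tp <- sub(".*_(10|60)$", "\\1", col)
    suv <- samples[[paste0("suv", tp)]]
    bg <- pan[[.FEATURE_BACKGROUND[[col]]]]
    if (any(!is.na(bg) & bg <= 0)) stop("invalid background")
    out[[col]] <- suv / bg
  }
  out$module <- abs(out$tbr_plexus_10 - out$tbr_plexus_60)

  if (completeCase) {
    keep <- stats::complete.cases(out[c("suv10", "suv60", .FEATURE_COLS)])
    nDropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0L) stop("no complete cases")
    rownames(out) <- NULL
    attr(out, "nDropped") <- nDropped
  } else {
    attr(out, "nDropped") <- 0L
  }
  out
}
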