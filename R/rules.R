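#' ThresholdRule: a single-feature cutoff classifier
#'
#' Labels a sample tumor when its feature value exceeds the cutoff
#' (strictly by default; inclusively when \code{inclusive}). Higher values
#' always point toward tumor.
#'
#' @slot feature feature (column) name the rule reads.
#' @slot cutoff positive cutoff on the feature.
#' @slot inclusive logical; use >= instead of >.
#' @exportClass ThresholdRule
setClass("ThresholdRule",
         representation(feature = "character",
                        cutoff = "numeric",
                        inclusive = "logical"))

setValidity("ThresholdRule", function(object) {
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0)
    return("'cutoff' must be a positive scalar")
  TRUE
})

#' Construct a ThresholdRule
#'
#' @param feature feature name (e.g. \code{"tbr_brain_60"}).
#' @param cutoff positive cutoff.
#' @param inclusive call tumor at values equal to the cutoff (default
#'   FALSE: strictly greater).
#' @return A \linkS4class{ThresholdRule}.
#' @examples
#' thresholdRule("tbr_brain_60", 1.6)
#' @export
thresholdRule <- function(feature, cutoff, inclusive = FALSE) {
  new("ThresholdRule", feature = feature, cutoff = cutoff,
      inclusive = inclusive)
}

setMethod("show", "ThresholdRule", function(object) {
  cat(sprintf("ThresholdRule: tumor iff %s %s %.4g\n", object@feature,
              if (object@inclusive) ">=" else ">", object@cutoff))
})

#' Apply a threshold rule
#'
#' @param x numeric vector of feature values, or a \code{data.frame}
#'   holding the rule's feature column.
#' @param rule a \linkS4class{ThresholdRule}.
#' @return Character vector of labels, \code{"tumor"} or
#'   \code{"astrogliosis"}.
#' @examples
#' applyThresholdRule(c(1.7, 1.5), thresholdRule("tbr_brain_60", 1.6))
#' @export
applyThresholdRule <- function(x, rule) {
  stopifnot(is(rule, "ThresholdRule"))
  if (is.data.frame(x)) {
    if (!rule@feature %in% names(x))
      stop(sprintf("unknown feature '%s'", rule@feature))
    x <- x[[rule@feature]]
  }
  hit <- if (rule@inclusive) x >= rule@cutoff else x > rule@cutoff
  ifelse(hit, "tumor", "astrogliosis")
}

#' Dual-acquisition plexus rule
#'
#' Calls tumor when the early plexus TBR exceeds 1.0 or the late plexus
#' TBR exceeds 1.2 (disjunction of the two single-timepoint rules, which
#' raises sensitivity at the price of specificity relative to the late
#' acquisition alone).
#'
#' @param row \code{data.frame} (or list) with \code{tbr_plexus_10} and
#'   \code{tbr_plexus_60}; vectorized over rows.
#' @return Character vector of labels.
#' @examples
#' dualPlexusRule(data.frame(tbr_plexus_10 = 0.9, tbr_plexus_60 = 1.3))
#' @export
dualPlexusRule <- function(row) {
  for (f in c("tbr_plexus_10", "tbr_plexus_60")) {
    if (is.null(row[[f]]) || any(is.na(row[[f]])))
      stop(sprintf("missing feature '%s'", f))
  }
  cut <- decisionThresholds()$dual_plexus
  ifelse(row[["tbr_plexus_10"]] > cut$early |
           row[["tbr_plexus_60"]] > cut$late,
         "tumor", "astrogliosis")
}

#' Published decision-tree classifier
#'
#' The published two-branch tree over the late plexus TBR and the
#' dual-timepoint \code{module} feature: tumor when the late plexus TBR
#' exceeds 1.77 and the module exceeds 1.11, or when the late plexus TBR
#' lies in (1.05, 1.77] and the module is below 3.19; astrogliosis
#' otherwise. The boundary value 1.77 itself belongs to the second
#' branch; 1.05 falls on the astrogliosis side.
#'
#' @param tbrPlexus60 late-acquisition plexus TBR, non-negative;
#'   vectorized.
#' @param module absolute difference of the early and late plexus TBR,
#'   non-negative; vectorized.
#' @return Character vector of labels.
#' @examples
#' publishedTreeClassify(c(2.0, 1.5, 0.9), c(1.5, 1.0, 5.0))
#' @export
publishedTreeClassify <- function(tbrPlexus60, module) {
  if (any(!is.finite(tbrPlexus60)) || any(!is.finite(module)) ||
      any(tbrPlexus60 < 0) || any(module < 0))
    stop("inputs must be non-negative")
  k <- decisionThresholds()$published_tree
  highBranch <- tbrPlexus60 > k$plexus60_hi & module > k$module_hi
  midBranch <- tbrPlexus60 > k$plexus60_lo & tbrPlexus60 <= k$plexus60_hi &
    module < k$module_cap
  ifelse(highBranch | midBranch, "tumor", "astrogliosis")
}

#' Thalamus infiltration rule
#'
#' Flags pathological uptake within the thalamus. Absolute mode compares
#' the SUV against 1.0 (early) or 1.1 (late), strictly; relative mode
#' compares the ratio to the contralateral thalamus against 1.7 (early) or
#' 1.6 (late), inclusively.
#'
#' @param value SUV (absolute mode) or ratio to contralateral thalamus
#'   (relative mode); non-negative, vectorized.
#' @param timepoint \code{"T10"} or \code{"T60"}.
#' @param mode \code{"absolute"} or \code{"relative"}.
#' @return Character vector, \code{"pathological"} or \code{"normal"}.
#' @examples
#' thalamusRule(1.6, "T60", "relative")
#' thalamusRule(1.05, "T60", "absolute")
#' @export
thalamusRule <- function(value, timepoint = c("T10", "T60"),
                         mode = c("absolute", "relative")) {
  timepoint <- match.arg(timepoint)
  mode <- match.arg(mode)
  if (any(!is.finite(value)) || any(value < 0))
    stop("value must be non-negative")
  thr <- decisionThresholds()
  early <- timepoint == "T10"
  if (mode == "absolute") {
    cut <- if (early) thr$thalamus_absolute$early else
      thr$thalamus_absolute$late
    hit <- value > cut
  } else {
    cut <- if (early) thr$thalamus_relative$early else
      thr$thalamus_relative$late
    hit <- value >= cut
  }
  ifelse(hit, "pathological", "normal")
}
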