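.DELINEATION_METHODS <- c("brain16_standard", "plexus_mean_early_10",
                          "plexus_late_12", "dual_plexus", "thalamus_abs")

#' DelineationRule: a voxelwise tumor-extent rule
#'
#' @slot method one of \code{"brain16_standard"} (late volume over brain
#'   VOI mean > 1.6), \code{"plexus_mean_early_10"} (early volume over
#'   plexus ROI mean > 1.0), \code{"plexus_late_12"} (late volume over
#'   plexus max > 1.2), \code{"dual_plexus"} (union of the two plexus
#'   masks), \code{"thalamus_abs"} (late volume above the absolute
#'   thalamus SUV threshold 1.1).
#' @slot restrictTo optional logical mask the result is intersected with
#'   (e.g. the FLAIR-hyperintense region).
#' @exportClass DelineationRule
setClass("DelineationRule",
         representation(method = "character", restrictTo = "ANY"))

setValidity("DelineationRule", function(object) {
  if (!object@method %in% .DELINEATION_METHODS)
    return(paste("'method' must be one of:",
                 paste(.DELINEATION_METHODS, collapse = ", ")))
  if (!is.null(object@restrictTo) &&
      (!is.logical(object@restrictTo) ||
       length(dim(object@restrictTo)) != 3L))
    return("'restrictTo' must be NULL or a logical 3-D mask")
  TRUE
})

#' Construct a DelineationRule
#'
#' @param method rule name; see \linkS4class{DelineationRule}.
#' @param restrictTo optional logical 3-D mask to intersect with.
#' @return A \linkS4class{DelineationRule}.
#' @examples
#' delineationRule("plexus_mean_early_10")
#' @export
delineationRule <- function(method = .DELINEATION_METHODS,
                            restrictTo = NULL) {
  method <- match.arg(method)
  new("DelineationRule", method = method, restrictTo = restrictTo)
}

#' Voxelwise target-to-background ratio map
#'
#' @param volume an \linkS4class{SUVVolume} (or numeric 3-D array).
#' @param background positive scalar background SUV.
#' @return Numeric 3-D array of ratios on the same grid.
#' @examples
#' v <- SUVVolume(array(0.96, c(4, 4, 4)))
#' tbrMap(v, 0.60)[1, 1, 1]
#' @export
tbrMap <- function(volume, background) {
  if (length(background) != 1L || !is.finite(background) || background <= 0)
    stop("invalid background")
  vals <- if (is(volume, "SUVVolume")) suvValues(volume) else volume
  stopifnot(length(dim(vals)) == 3L)
  vals / background
}

#' Delineate tumor extent on a dual-timepoint volume pair
#'
#' Applies one of the voxelwise threshold rules, reading its background
#' scalar(s) from the reference panel (never from inside the candidate
#' tumor region), optionally restricted to a mask. No morphological
#' post-processing is applied: the mask is the raw threshold contour.
#'
#' @param vol10,vol60 \linkS4class{SUVVolume}s on the same grid.
#' @param panel a \linkS4class{ReferencePanel} for the patient.
#' @param rule a \linkS4class{DelineationRule} (or a method name).
#' @return A \linkS4class{DelineationMask} with provenance recording the
#'   rule, thresholds and background values used.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(seed = 1))
#' pan <- measureReferencePanel(ph$vol10, ph$vol60,
#'                              defaultPlacements(ph$spec))
#' m <- delineate(ph$vol10, ph$vol60, pan, "plexus_mean_early_10")
#' volumeMl(m)
#' @export
delineate <- function(vol10, vol60, panel, rule) {
  if (is.character(rule)) rule <- delineationRule(rule)
  stopifnot(is(rule, "DelineationRule"), is(panel, "ReferencePanel"))
  stopifnot(identical(dim(vol10), dim(vol60)))
  dec <- decisionThresholds()

  plexusEarly <- function() {
    bg <- panelValue(panel, "plexus", "mean", "T10")
    list(mask = tbrMap(vol10, bg) > dec$dual_plexus$early,
         background = c(plexus_mean_10 = bg),
         threshold = dec$dual_plexus$early)
  }
  plexusLate <- function() {
    bg <- panelValue(panel, "plexus", "max", "T60")
    list(mask = tbrMap(vol60, bg) > dec$dual_plexus$late,
         background = c(plexus_max_60 = bg),
         threshold = dec$dual_plexus$late)
  }

  res <- switch(
    rule@method,
    brain16_standard = {
      bg <- panelValue(panel, "brain", "mean", "T60")
      list(mask = tbrMap(vol60, bg) > dec$brain_tbr,
           background = c(brain_mean_60 = bg), threshold = dec$brain_tbr)
    },
    plexus_mean_early_10 = plexusEarly(),
    plexus_late_12 = plexusLate(),
    dual_plexus = {
      a <- plexusEarly()
      b <- plexusLate()
      list(mask = a$mask | b$mask,
           background = c(a$background, b$background),
           threshold = c(early = a$threshold, late = b$threshold))
    },
    thalamus_abs = {
      thr <- dec$thalamus_absolute$late
      list(mask = suvValues(vol60) > thr, background = numeric(0),
           threshold = thr)
    })

  mask <- res$mask
  restricted <- FALSE
  if (!is.null(rule@restrictTo)) {
    stopifnot(identical(dim(rule@restrictTo), dim(mask)))
    mask <- mask & rule@restrictTo
    restricted <- TRUE
  }
  new("DelineationMask", mask = mask, voxelSize = voxelSize(vol10),
      provenance = list(method = rule@method, threshold = res$threshold,
                        background = res$background,
                        restricted = restricted))
}

#' Overlap metrics between two masks
#'
#' @param maskA,maskB \linkS4class{DelineationMask}s or logical 3-D
#'   arrays on the same grid.
#' @param voxelSize voxel edge lengths in mm when plain arrays are given.
#' @return A list with \code{dice} (2|A n B| / (|A| + |B|); 1 when both
#'   masks are empty), \code{volumeAMl}, \code{volumeBMl} and
#'   \code{aMinusBMl} (volume of A outside B).
#' @examples
#' a <- array(TRUE, c(2, 2, 2)); b <- a
#' maskMetrics(a, b, voxelSize = 2)$dice
#' @export
maskMetrics <- function(maskA, maskB, voxelSize = c(1, 1, 1)) {
  unwrap <- function(m) {
    if (is(m, "DelineationMask")) list(mask = m@mask, vs = m@voxelSize)
    else list(mask = m, vs = if (length(voxelSize) == 1L)
      rep(voxelSize, 3L) else voxelSize)
  }
  a <- unwrap(maskA)
  b <- unwrap(maskB)
  if (!identical(dim(a$mask), dim(b$mask)) ||
      !isTRUE(all.equal(a$vs, b$vs)))
    stop("grid mismatch")
  voxMl <- prod(a$vs) / 1000
  nA <- sum(a$mask)
  nB <- sum(b$mask)
  nAB <- sum(a$mask & b$mask)
  dice <- if (nA + nB == 0) 1 else 2 * nAB / (nA + nB)
  list(dice = dice, volumeAMl = nA * voxMl, volumeBMl = nB * voxMl,
       aMinusBMl = sum(a$mask & !b$mask) * voxMl)
}
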