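#' @import methods
NULL

## Controlled vocabularies used across the package.
.TISSUES <- c("brain", "thalamus", "plexus", "sinus", "artery",
              "astrogliosis", "G2", "G3", "G4")
.TUMOR_TISSUES <- c("G2", "G3", "G4")
.HISTOLOGY <- c("astrogliosis", "G2", "G3", "G4")
.TRAJECTORIES <- c("T1-GAD", "PET", "PET-", "FLAIR")
.TIMEPOINTS <- c("T10", "T60")

## Panel entries: structure x statistic x timepoint combinations that the
## reference workflow measures (brain/thalamus/plexus carry mean and max,
## artery and sinus are read as maxima only).
.PANEL_ENTRIES <- as.vector(outer(
  c("brain_mean", "brain_max", "thalamus_mean", "thalamus_max",
    "plexus_mean", "plexus_max", "artery_max", "sinus_max"),
  c("10", "60"), paste, sep = "_"))

#' SUVVolume: a 3-D standardized-uptake-value grid
#'
#' Container for one reconstructed PET volume expressed in standardized
#' uptake values (SUV, unitless, body-weight normalized), together with its
#' voxel spacing in mm and the acquisition timepoint tag. \code{"T10"}
#' labels the early acquisition (about 10 min after injection) and
#' \code{"T60"} the standard late acquisition (40--60 min).
#'
#' @slot values numeric 3-D array of SUVs; finite and non-negative.
#' @slot voxelSize numeric length-3 voxel edge lengths in mm, all positive.
#' @slot timepoint character, one of \code{"T10"}, \code{"T60"}.
#' @exportClass SUVVolume
setClass("SUVVolume",
         representation(values = "array",
                        voxelSize = "numeric",
                        timepoint = "character"))

setValidity("SUVVolume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3-D array")
  if (!all(is.finite(v)))
    return("all SUVs must be finite")
  if (any(v < 0))
    return("SUVs must be non-negative")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("'voxelSize' must be three positive values (mm)")
  if (length(object@timepoint) != 1L ||
      !object@timepoint %in% .TIMEPOINTS)
    return("'timepoint' must be one of \"T10\", \"T60\"")
  TRUE
})

#' Construct an SUVVolume
#'
#' @param values numeric 3-D array of SUVs.
#' @param voxelSize voxel edge lengths in mm; a scalar is recycled to the
#'   three axes.
#' @param timepoint acquisition tag, \code{"T10"} or \code{"T60"}.
#' @return An \linkS4class{SUVVolume}.
#' @examples
#' vol <- SUVVolume(array(1, c(4, 4, 4)), voxelSize = 2, timepoint = "T10")
#' dim(vol)
#' @export
SUVVolume <- function(values, voxelSize = c(2, 2, 2), timepoint = "T10") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("SUVVolume", values = values, voxelSize = as.numeric(voxelSize),
      timepoint = timepoint)
}

#' @describeIn SUVVolume grid dimensions (voxels per axis).
#' @param x an \code{SUVVolume}.
#' @export
setMethod("dim", "SUVVolume", function(x) dim(x@values))

setMethod("show", "SUVVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("SUVVolume [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@timepoint, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  SUV range: %.3f .. %.3f\n",
              min(object@values), max(object@values)))
})

#' @rdname suvValues
#' @export
setGeneric("suvValues", function(x) standardGeneric("suvValues"))

#' Extract the raw SUV array
#'
#' @param x an \linkS4class{SUVVolume}.
#' @return The numeric 3-D array of SUVs.
#' @export
setMethod("suvValues", "SUVVolume", function(x) x@values)

#' @rdname voxelSize
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel spacing in mm
#'
#' @param x an \linkS4class{SUVVolume} or \linkS4class{DelineationMask}.
#' @return Numeric length-3 vector of voxel edge lengths (mm).
#' @export
setMethod("voxelSize", "SUVVolume", function(x) x@voxelSize)

#' @rdname timepoint
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))

#' Acquisition timepoint tag
#'
#' @param x an \linkS4class{SUVVolume}.
#' @return \code{"T10"} or \code{"T60"}.
#' @export
setMethod("timepoint", "SUVVolume", function(x) x@timepoint)

## Allowed nominal-volume ranges (cm^3) per named reference structure.
.VOI_RANGES <- list(
  brain    = list(shape = "sphere", range = c(10, 20)),
  artery   = list(shape = "circle", range = c(0.003, 0.005)),
  sinus    = list(shape = "sphere", range = c(0.3, 0.8)),
  thalamus = list(shape = "sphere", range = c(0.5, 1)),
  plexus   = list(shape = "circle", range = c(0.3, 0.6)))

#' VOISpec: a sphere VOI or circle ROI placement
#'
#' Geometric specification of a volume/region of interest: a sphere of a
#' nominal volume, or a single-plane circle (disc one voxel-plane thick).
#' Nominal volumes for the named reference structures are constrained to
#' the conventional per-structure ranges (brain sphere 10--20 cm^3, artery
#' circle 3--5 mm^3, sinus sphere 0.3--0.8 cm^3, thalamus sphere 0.5--1
#' cm^3, plexus circle 0.3--0.6 cm^3).
#'
#' @slot structure character name of the structure measured.
#' @slot shape \code{"sphere"} or \code{"circle"}.
#' @slot center numeric length-3 world coordinates in mm.
#' @slot volumeCm3 nominal volume in cm^3.
#' @slot planeAxis axis normal to the circle plane (1, 2 or 3; circles only).
#' @exportClass VOISpec
setClass("VOISpec",
         representation(structure = "character",
                        shape = "character",
                        center = "numeric",
                        volumeCm3 = "numeric",
                        planeAxis = "integer"))

setValidity("VOISpec", function(object) {
  if (!object@shape %in% c("sphere", "circle"))
    return("'shape' must be \"sphere\" or \"circle\"")
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    return("'center' must be three finite mm coordinates")
  if (length(object@volumeCm3) != 1L || !is.finite(object@volumeCm3) ||
      object@volumeCm3 <= 0)
    return("'volumeCm3' must be a positive scalar")
  if (object@shape == "circle" &&
      (length(object@planeAxis) != 1L || !object@planeAxis %in% 1:3))
    return("'planeAxis' must be 1, 2 or 3")
  known <- .VOI_RANGES[[object@structure]]
  if (!is.null(known)) {
    if (object@shape != known$shape)
      return(sprintf("structure '%s' uses a %s", object@structure,
                     known$shape))
    rng <- known$range
    if (object@volumeCm3 < rng[1] || object@volumeCm3 > rng[2])
      return(sprintf(
        "nominal volume for '%s' must lie in [%g, %g] cm^3",
        object@structure, rng[1], rng[2]))
  }
  TRUE
})

#' Construct a VOISpec
#'
#' For the named reference structures the shape defaults to the
#' conventional one (sphere for brain/sinus/thalamus, circle for
#' artery/plexus). An artery circle of 3--5 mm^3 is below typical scanner
#' resolution; it is allowed, with a warning.
#'
#' @param structure structure name (free text; known names are
#'   range-checked).
#' @param center numeric length-3 world coordinates in mm.
#' @param volumeCm3 nominal volume in cm^3.
#' @param shape \code{"sphere"} or \code{"circle"}; default chosen from the
#'   structure name when known, otherwise sphere.
#' @param planeAxis axis normal to the circle plane; default 3 (axial).
#' @return A \linkS4class{VOISpec}.
#' @examples
#' voiSpec("brain", center = c(30, 30, 30), volumeCm3 = 15)
#' @export
voiSpec <- function(structure, center, volumeCm3, shape = NULL,
                    planeAxis = 3L) {
  known <- .VOI_RANGES[[structure]]
  if (is.null(shape))
    shape <- if (is.null(known)) "sphere" else known$shape
  if (structure == "artery")
    warning("artery ROI nominal volume is below typical scanner resolution",
            call. = FALSE)
  new("VOISpec", structure = structure, shape = shape,
      center = as.numeric(center), volumeCm3 = volumeCm3,
      planeAxis = as.integer(planeAxis))
}

setMethod("show", "VOISpec", function(object) {
  cat(sprintf("VOISpec '%s': %s, %.3g cm^3 at (%.1f, %.1f, %.1f) mm\n",
              object@structure, object@shape, object@volumeCm3,
              object@center[1], object@center[2], object@center[3]))
})

#' ReferencePanel: per-patient background measurements
#'
#' Reference-structure uptake for one patient at both timepoints:
#' contralateral brain mean/max, thalamus mean/max, choroid plexus
#' mean/max, middle cerebral artery max and venous sinus max, each at the
#' early (10 min) and late (60 min) acquisition.
#'
#' @slot patientId character patient identifier.
#' @slot values named numeric vector with entries
#'   \code{brain_mean_10, brain_max_10, ..., sinus_max_60} (see
#'   \code{fetquant:::.PANEL_ENTRIES}).
#' @exportClass ReferencePanel
setClass("ReferencePanel",
         representation(patientId = "character", values = "numeric"))

setValidity("ReferencePanel", function(object) {
  v <- object@values
  missing <- setdiff(.PANEL_ENTRIES, names(v))
  if (length(missing))
    return(paste("missing reference measurement:",
                 paste(missing, collapse = ", ")))
  present <- v[.PANEL_ENTRIES]
  bad <- present[!is.na(present) & present <= 0]
  if (length(bad))
    return("reference SUVs must be positive")
  for (s in c("brain", "thalamus", "plexus")) {
    for (tp in c("10", "60")) {
      mx <- v[paste(s, "max", tp, sep = "_")]
      mn <- v[paste(s, "mean", tp, sep = "_")]
      if (!is.na(mx) && !is.na(mn) && mx < mn - 1e-12)
        return(sprintf("%s max must be >= %s mean (timepoint %s)", s, s, tp))
    }
  }
  TRUE
})

#' Construct a ReferencePanel
#'
#' @param values named numeric vector covering all panel entries
#'   (\code{brain_mean_10}, ..., \code{sinus_max_60}); \code{NA} marks a
#'   missing measurement.
#' @param patientId patient identifier.
#' @return A \linkS4class{ReferencePanel}.
#' @export
ReferencePanel <- function(values, patientId = "P01") {
  new("ReferencePanel", patientId = patientId,
      values = values[.PANEL_ENTRIES])
}

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel for %s\n", object@patientId))
  print(round(object@values, 3))
})

#' @rdname panelValue
#' @export
setGeneric("panelValue", function(panel, structure, statistic, timepoint)
  standardGeneric("panelValue"))

#' Look up one reference measurement
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param structure one of \code{"brain"}, \code{"thalamus"},
#'   \code{"plexus"}, \code{"artery"}, \code{"sinus"}.
#' @param statistic \code{"mean"} or \code{"max"}.
#' @param timepoint \code{"T10"} or \code{"T60"} (also accepts \code{"10"} /
#'   \code{"60"}).
#' @return The SUV, or an error if that entry is absent or missing.
#' @export
setMethod("panelValue", "ReferencePanel",
          function(panel, structure, statistic, timepoint) {
  tp <- sub("^T", "", as.character(timepoint))
  key <- paste(structure, statistic, tp, sep = "_")
  if (!key %in% names(panel@values))
    stop(sprintf("no panel entry '%s'", key))
  val <- unname(panel@values[key])
  if (is.na(val))
    stop(sprintf("missing reference measurement: %s", key))
  val
})

#' Coerce a ReferencePanel to a one-row data.frame
#'
#' @param x a \linkS4class{ReferencePanel}.
#' @param ... ignored.
#' @return A one-row \code{data.frame} with \code{patient_id} and the 16
#'   panel entries.
#' @export
setMethod("as.data.frame", "ReferencePanel", function(x, ...) {
  out <- as.data.frame(as.list(x@values))
  cbind(data.frame(patient_id = x@patientId, stringsAsFactors = FALSE), out)
})

#' UptakeModel: tissue-wise SUV distribution summaries
#'
#' Per (tissue, timepoint) five-number summaries (min, lower quartile,
#' median, upper quartile, max) of the SUV, plus the sampling family used
#' to turn the summaries into draws and the Gaussian-copula correlation
#' coupling the two timepoints within a sample.
#'
#' @slot quantiles data.frame with columns \code{tissue}, \code{timepoint}
#'   (\code{"10"}/\code{"60"}), \code{median}, \code{lower_q},
#'   \code{upper_q}, \code{min}, \code{max}.
#' @slot family \code{"quantile"} (piecewise log-linear interpolation of
#'   the printed quantiles; the default) or \code{"lognormal"} (truncated
#'   lognormal matched to median and IQR).
#' @slot copulaRho correlation of the latent Gaussian scores of the two
#'   timepoints, in [0, 1).
#' @exportClass UptakeModel
setClass("UptakeModel",
         representation(quantiles = "data.frame",
                        family = "character",
                        copulaRho = "numeric"))

setValidity("UptakeModel", function(object) {
  q <- object@quantiles
  need <- c("tissue", "timepoint", "median", "lower_q", "upper_q",
            "min", "max")
  if (!all(need %in% names(q)))
    return(paste("quantile table needs columns:", paste(need, collapse = ", ")))
  num <- q[c("min", "lower_q", "median", "upper_q", "max")]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) <= 0))
    return("all SUV summaries must be positive and finite")
  ok <- q$min <= q$lower_q + 1e-12 & q$lower_q <= q$median + 1e-12 &
    q$median <= q$upper_q + 1e-12 & q$upper_q <= q$max + 1e-12
  if (!all(ok))
    return("each row must satisfy min <= lower_q <= median <= upper_q <= max")
  if (anyDuplicated(paste(q$tissue, q$timepoint)))
    return("duplicate (tissue, timepoint) rows")
  if (!object@family %in% c("quantile", "lognormal"))
    return("'family' must be \"quantile\" or \"lognormal\"")
  if (object@copulaRho < 0 || object@copulaRho >= 1)
    return("'copulaRho' must lie in [0, 1)")
  TRUE
})

setMethod("show", "UptakeModel", function(object) {
  cat(sprintf("UptakeModel (%s family, copula rho = %.2f): %d tissue rows\n",
              object@family, object@copulaRho, nrow(object@quantiles)))
  cat("  tissues:", paste(sort(unique(object@quantiles$tissue)),
                          collapse = ", "), "\n")
})

#' PhantomSpec: geometry of a synthetic dual-timepoint phantom
#'
#' Describes a rectangular SUV grid holding a concentric tumor complex
#' (core ellipsoid of a chosen grade, a G2 shell, an astrogliosis shell,
#' all inside a FLAIR-hyperintense ellipsoid with a contrast-enhancing
#' subset) in one hemisphere, and spherical reference structures
#' (thalamus, choroid plexus, venous sinus, middle cerebral artery) in the
#' contralateral hemisphere, with background brain filling the rest.
#'
#' @slot gridShape integer length-3 voxels per axis.
#' @slot voxelSize isotropic voxel edge length, mm.
#' @slot structures data.frame with columns \code{structure}, \code{x},
#'   \code{y}, \code{z} (center, mm) and \code{r} (radius, mm) for the
#'   spherical reference structures.
#' @slot tumorCenter numeric length-3 center of the tumor complex, mm.
#' @slot coreRadii,g2Radii,astroRadii,flairRadii,ceRadii numeric length-3
#'   ellipsoid semi-axes, mm; nested core < G2 < astrogliosis <= FLAIR,
#'   CE <= FLAIR.
#' @slot coreGrade tissue class of the core (\code{"G3"} or \code{"G4"}).
#' @slot noiseSd additive Gaussian voxel noise, SUV units.
#' @slot seed integer seed (NA for none).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(gridShape = "integer",
                        voxelSize = "numeric",
                        structures = "data.frame",
                        tumorCenter = "numeric",
                        coreRadii = "numeric",
                        g2Radii = "numeric",
                        astroRadii = "numeric",
                        flairRadii = "numeric",
                        ceRadii = "numeric",
                        coreGrade = "character",
                        noiseSd = "numeric",
                        seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("'gridShape' must be three axis lengths of at least 8 voxels")
  if (object@voxelSize <= 0)
    return("'voxelSize' must be positive")
  st <- object@structures
  if (!all(c("structure", "x", "y", "z", "r") %in% names(st)))
    return("'structures' needs columns structure, x, y, z, r")
  minR <- 2 * object@voxelSize
  allRadii <- c(st$r, object@coreRadii, object@g2Radii, object@astroRadii,
                object@flairRadii, object@ceRadii)
  if (any(allRadii < minR))
    return(sprintf("all radii must be at least 2 voxels (%.3g mm)", minR))
  if (!all(object@ceRadii <= object@flairRadii))
    return("CE region must lie inside the FLAIR region")
  if (!all(object@astroRadii <= object@flairRadii))
    return("astrogliosis shell must lie inside the FLAIR region")
  if (!(all(object@coreRadii < object@g2Radii) &&
        all(object@g2Radii < object@astroRadii)))
    return("tumor ellipsoids must be strictly nested: core < G2 < astrogliosis")
  if (!object@coreGrade %in% c("G3", "G4"))
    return("'coreGrade' must be \"G3\" or \"G4\"")
  if (object@noiseSd < 0)
    return("'noiseSd' must be non-negative")
  ## pairwise disjointness of spherical structures
  if (nrow(st) > 1) {
    for (i in seq_len(nrow(st) - 1)) {
      for (j in (i + 1):nrow(st)) {
        d <- sqrt(sum((unlist(st[i, c("x", "y", "z")]) -
                       unlist(st[j, c("x", "y", "z")]))^2))
        if (d <= st$r[i] + st$r[j])
          return("structures must be disjoint")
      }
    }
  }
  ## structures must not touch the tumor/FLAIR complex
  fmax <- max(object@flairRadii)
  for (i in seq_len(nrow(st))) {
    d <- sqrt(sum((unlist(st[i, c("x", "y", "z")]) - object@tumorCenter)^2))
    if (d <= st$r[i] + fmax)
      return("structures must be disjoint")
  }
  ## everything must fit inside the grid
  ext <- object@gridShape * object@voxelSize
  tumorLo <- object@tumorCenter - object@flairRadii
  tumorHi <- object@tumorCenter + object@flairRadii
  stLo <- c(min(st$x - st$r), min(st$y - st$r), min(st$z - st$r))
  stHi <- c(max(st$x + st$r), max(st$y + st$r), max(st$z + st$r))
  if (any(pmin(tumorLo, stLo) < 0) || any(pmax(tumorHi, stHi) > ext))
    return("geometry does not fit inside the grid")
  TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d x %d voxels at %.3g mm, core grade %s, noise sd %.3g\n",
    object@gridShape[1], object@gridShape[2], object@gridShape[3],
    object@voxelSize, object@coreGrade, object@noiseSd))
})

#' CartTree: a fitted classification tree
#'
#' Binary recursive-partitioning tree with Gini split selection. Each node
#' stores its split (feature and threshold, rows with value <= threshold
#' go left), training class counts, the majority-class prediction, and a
#' Fisher-exact p-value for class membership inside versus outside the
#' node. Tree-level costs are the resubstitution misclassification rate
#' and the V-fold cross-validation cost with its standard error.
#'
#' @slot nodes data.frame of node records (id, depth, n, feature,
#'   threshold, children, prediction, p-value, leaf flag).
#' @slot counts matrix of per-node class counts (rows align with nodes).
#' @slot classLevels character class labels.
#' @slot costs list with \code{resubstitution}, \code{cv}, \code{cvSE}.
#' @slot params list of fitting parameters.
#' @exportClass CartTree
setClass("CartTree",
         representation(nodes = "data.frame",
                        counts = "matrix",
                        classLevels = "character",
                        costs = "list",
                        params = "list"))

setMethod("show", "CartTree", function(object) {
  nl <- sum(object@nodes$is_leaf)
  cat(sprintf("CartTree: %d nodes (%d leaves), classes: %s\n",
              nrow(object@nodes), nl,
              paste(object@classLevels, collapse = ", ")))
  cat(sprintf("  resubstitution cost %.4f", object@costs$resubstitution))
  if (!is.null(object@costs$cv) && is.finite(object@costs$cv))
    cat(sprintf("; CV cost %.4f +- %.4f", object@costs$cv, object@costs$cvSE))
  cat("\n")
  nd <- object@nodes
  for (i in seq_len(nrow(nd))) {
    pad <- strrep("  ", nd$depth[i] + 1)
    if (nd$is_leaf[i]) {
      cat(sprintf("%s[%d] leaf -> %s (n=%d, p=%.3g)\n", pad, nd$id[i],
                  nd$prediction[i], nd$n[i], nd$p_value[i]))
    } else {
      cat(sprintf("%s[%d] %s <= %.4g ? left [%d] : right [%d] (n=%d)\n",
                  pad, nd$id[i], nd$feature[i], nd$threshold[i],
                  nd$left[i], nd$right[i], nd$n[i]))
    }
  }
})

#' ROCResult: an ROC analysis
#'
#' Operating points (sensitivity/specificity at each candidate cutoff,
#' prediction positive when score exceeds the cutoff), the Mann--Whitney
#' AUC with a 95\% confidence interval, and the Youden-optimal cutoff.
#'
#' @slot thresholds sorted candidate cutoffs (midpoints between adjacent
#'   distinct scores).
#' @slot sensitivity,specificity operating characteristics per threshold.
#' @slot auc area under the ROC curve.
#' @slot ciLow,ciHigh 95\% confidence bounds for the AUC.
#' @slot ciMethod \code{"delong"} or \code{"bootstrap"}.
#' @slot youden Youden-optimal cutoff.
#' @slot nPos,nNeg class sizes.
#' @exportClass ROCResult
setClass("ROCResult",
         representation(thresholds = "numeric",
                        sensitivity = "numeric",
                        specificity = "numeric",
                        auc = "numeric",
                        ciLow = "numeric",
                        ciHigh = "numeric",
                        ciMethod = "character",
                        youden = "numeric",
                        nPos = "integer",
                        nNeg = "integer"))

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1)
    return("AUC must lie in [0, 1]")
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@ciLow > object@auc + 1e-9 || object@ciHigh < object@auc - 1e-9))
    return("confidence interval must bracket the AUC")
  if (length(object@sensitivity) != length(object@thresholds) ||
      length(object@specificity) != length(object@thresholds))
    return("operating points must align with thresholds")
  TRUE
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROCResult: AUC %.3f (95%% CI %.3f-%.3f, %s), %d pos / %d neg\n",
    object@auc, object@ciLow, object@ciHigh, object@ciMethod,
    object@nPos, object@nNeg))
  cat(sprintf("  Youden-optimal cutoff: %.4g\n", object@youden))
})

#' @rdname auc
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' Area under the ROC curve
#'
#' @param x an \linkS4class{ROCResult}.
#' @return The AUC.
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)

#' DelineationMask: a voxelwise tumor-extent mask
#'
#' Binary volume on the same grid as its source SUV volume, together with
#' provenance (the rule, backgrounds and thresholds that produced it).
#'
#' @slot mask logical 3-D array.
#' @slot voxelSize numeric length-3 voxel edge lengths, mm.
#' @slot provenance list describing how the mask was produced.
#' @exportClass DelineationMask
setClass("DelineationMask",
         representation(mask = "array",
                        voxelSize = "numeric",
                        provenance = "list"))

setValidity("DelineationMask", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("'mask' must be a logical 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be three positive values (mm)")
  TRUE
})

#' @describeIn DelineationMask voxel spacing of the mask grid.
#' @param x a \code{DelineationMask}.
#' @export
setMethod("voxelSize", "DelineationMask", function(x) x@voxelSize)

#' @rdname volumeMl
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))

#' Mask volume in milliliters
#'
#' @param x a \linkS4class{DelineationMask}.
#' @return Voxel count times voxel volume, in ml.
#' @export
setMethod("volumeMl", "DelineationMask", function(x)
  sum(x@mask) * prod(x@voxelSize) / 1000)

setMethod("show", "DelineationMask", function(object) {
  cat(sprintf("DelineationMask (%s): %d voxels, %.2f ml\n",
              if (is.null(object@provenance$method)) "?" else
                object@provenance$method,
              sum(object@mask), volumeMl(object)))
})
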