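#' Default phantom geometry
#'
#' A 64 x 64 x 48 grid at 2 mm isotropic voxels. The tumor complex sits in
#' one hemisphere: a core ellipsoid of the chosen grade, a G2 shell, an
#' astrogliosis shell, a FLAIR-hyperintense ellipsoid containing all of
#' them, and a contrast-enhancing (CE) ellipsoid slightly larger than the
#' core. Spherical reference structures (thalamus, choroid plexus, venous
#' sinus, middle cerebral artery) sit in the contralateral hemisphere;
#' background brain fills everything else.
#'
#' @param gridShape voxels per axis (default \code{c(64, 64, 48)}).
#' @param voxelSize isotropic voxel edge, mm (default 2).
#' @param coreGrade tissue class of the tumor core, \code{"G3"} (default)
#'   or \code{"G4"}.
#' @param noiseSd additive Gaussian voxel noise, SUV (default 0.05).
#' @param seed optional integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' defaultPhantomSpec(seed = 1)
#' @export
defaultPhantomSpec <- function(gridShape = c(64, 64, 48), voxelSize = 2,
                               coreGrade = "G3", noiseSd = 0.05,
                               seed = NULL) {
  structures <- data.frame(
    structure = c("thalamus", "plexus", "sinus", "artery"),
    x = c(40, 40, 40, 21),
    y = c(64, 40, 88, 63),
    z = c(48, 48, 48, 47),
    r = c(6, 8, 5, 4),
    stringsAsFactors = FALSE)
  new("PhantomSpec",
      gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize),
      structures = structures,
      tumorCenter = c(90, 64, 48),
      coreRadii = c(10, 9, 8),
      g2Radii = c(16, 14, 13),
      astroRadii = c(22, 20, 18),
      flairRadii = c(26, 24, 22),
      ceRadii = c(12, 11, 10),
      coreGrade = coreGrade,
      noiseSd = noiseSd,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

## Voxel-center coordinate grids (world mm, centers at (index - 0.5) * size
## for 1-based indices).
.voxelCenters <- function(gridShape, voxelSize) {
  lapply(1:3, function(a) (seq_len(gridShape[a]) - 0.5) * voxelSize)
}

.ellipsoidMask <- function(gridShape, voxelSize, center, radii) {
  cc <- .voxelCenters(gridShape, voxelSize)
  dx2 <- ((cc[[1]] - center[1]) / radii[1])^2
  dy2 <- ((cc[[2]] - center[2]) / radii[2])^2
  dz2 <- ((cc[[3]] - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a dual-timepoint SUV phantom
#'
#' Builds the tissue label map from the phantom geometry, then fills the
#' voxels in two tiers reflecting what the calibrated summaries describe.
#' Normal structures (background brain, thalamus, plexus, sinus, artery)
#' receive one patient-level value per structure and timepoint — their
#' calibrated distributions summarize one measurement per patient — drawn
#' at a single shared latent quantile so the physiologic ordering of the
#' structures (e.g. plexus above brain) holds within the phantom patient.
#' Lesional tissues (astrogliosis, G2, G3, G4) are heterogeneous, so each
#' voxel gets an independent draw from the per-sample distribution, with
#' the two timepoints coupled per voxel through the model's copula.
#' Additive Gaussian voxel noise (clipped at zero) is applied to both
#' tiers. Both timepoints share the geometry; generation is deterministic
#' under the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param model an \linkS4class{UptakeModel}.
#' @return A list with elements \code{vol10} and \code{vol60}
#'   (\linkS4class{SUVVolume}s), \code{labels} (integer array of tissue
#'   codes), \code{tissueLevels} (code -> tissue name), \code{flair} and
#'   \code{ce} (logical masks), \code{tissueValues} (the patient-level
#'   SUVs assigned to the normal structures), and \code{spec}.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(seed = 1, noiseSd = 0))
#' table(ph$tissueLevels[ph$labels])["plexus"]
#' @export
generatePhantom <- function(spec, model = defaultUptakeModel()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  gs <- spec@gridShape
  vs <- spec@voxelSize
  tissueLevels <- .TISSUES
  labels <- array(match("brain", tissueLevels), dim = gs)

  astro <- .ellipsoidMask(gs, vs, spec@tumorCenter, spec@astroRadii)
  g2 <- .ellipsoidMask(gs, vs, spec@tumorCenter, spec@g2Radii)
  core <- .ellipsoidMask(gs, vs, spec@tumorCenter, spec@coreRadii)
  labels[astro] <- match("astrogliosis", tissueLevels)
  labels[g2] <- match("G2", tissueLevels)
  labels[core] <- match(spec@coreGrade, tissueLevels)

  cc <- .voxelCenters(gs, vs)
  for (i in seq_len(nrow(spec@structures))) {
    st <- spec@structures[i, ]
    dx2 <- (cc[[1]] - st$x)^2
    dy2 <- (cc[[2]] - st$y)^2
    dz2 <- (cc[[3]] - st$z)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= st$r^2
    labels[inside] <- match(st$structure, tissueLevels)
  }

  flair <- .ellipsoidMask(gs, vs, spec@tumorCenter, spec@flairRadii)
  ce <- .ellipsoidMask(gs, vs, spec@tumorCenter, spec@ceRadii)

  normalTissues <- c("brain", "thalamus", "plexus", "sinus", "artery")
  draw <- function() {
    v10 <- array(0, dim = gs)
    v60 <- array(0, dim = gs)
    ## one patient-level quantile shared by all normal structures
    uPatient <- stats::runif(1)
    tissueValues <- data.frame(tissue = normalTissues,
                               suv10 = NA_real_, suv60 = NA_real_,
                               stringsAsFactors = FALSE)
    for (code in sort(unique(as.vector(labels)))) {
      tissue <- tissueLevels[code]
      idx <- which(labels == code)
      if (tissue %in% normalTissues) {
        s10 <- .suvQuantile(uPatient, .uptakeRow(model, tissue, "10"),
                            model@family)
        s60 <- .suvQuantile(uPatient, .uptakeRow(model, tissue, "60"),
                            model@family)
        v10[idx] <- s10
        v60[idx] <- s60
        tissueValues$suv10[tissueValues$tissue == tissue] <- s10
        tissueValues$suv60[tissueValues$tissue == tissue] <- s60
      } else {
        draws <- sampleUptake(model, tissue, length(idx))
        v10[idx] <- draws$suv10
        v60[idx] <- draws$suv60
      }
    }
    if (spec@noiseSd > 0) {
      v10 <- v10 + stats::rnorm(length(v10), 0, spec@noiseSd)
      v60 <- v60 + stats::rnorm(length(v60), 0, spec@noiseSd)
    }
    list(v10 = pmax(v10, 0), v60 = pmax(v60, 0),
         tissueValues = tissueValues)
  }
  vols <- if (is.na(spec@seed)) draw() else withr::with_seed(spec@seed, draw())

  list(vol10 = SUVVolume(vols$v10, voxelSize = vs, timepoint = "T10"),
       vol60 = SUVVolume(vols$v60, voxelSize = vs, timepoint = "T60"),
       labels = labels, tissueLevels = tissueLevels,
       flair = flair, ce = ce, tissueValues = vols$tissueValues,
       spec = spec)
}

#' True tumor compartment of a phantom
#'
#' @param phantom the list returned by \code{\link{generatePhantom}}.
#' @return Logical mask of voxels labeled G2, G3 or G4.
#' @export
phantomTumorMask <- function(phantom) {
  array(phantom$tissueLevels[phantom$labels] %in% .TUMOR_TISSUES,
        dim = dim(phantom$labels))
}

#' Default VOI/ROI placements for a phantom
#'
#' Places the reference VOIs/ROIs at the phantom's structure centers, plus
#' a contralateral-brain sphere in plain background, with conventional
#' nominal volumes (brain 15 cm^3, thalamus 0.75 cm^3, sinus 0.3 cm^3,
#' plexus circle 0.3 cm^3, artery circle 4 mm^3).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return Named list of \linkS4class{VOISpec} objects for brain,
#'   thalamus, plexus, sinus and artery.
#' @export
defaultPlacements <- function(spec = defaultPhantomSpec()) {
  st <- spec@structures
  centerOf <- function(name) {
    row <- st[st$structure == name, ]
    c(row$x, row$y, row$z)
  }
  list(
    brain = voiSpec("brain", center = c(24, 104, 48), volumeCm3 = 15),
    thalamus = voiSpec("thalamus", center = centerOf("thalamus"),
                       volumeCm3 = 0.75),
    plexus = voiSpec("plexus", center = centerOf("plexus"),
                     volumeCm3 = 0.3),
    sinus = voiSpec("sinus", center = centerOf("sinus"), volumeCm3 = 0.3),
    artery = suppressWarnings(
      voiSpec("artery", center = centerOf("artery"), volumeCm3 = 0.004)))
}
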