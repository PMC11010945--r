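## Geometry conventions: world coordinates are continuous mm with the grid
## corner at the origin; the center of voxel (i, j, k) (1-based) lies at
## ((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz).

.sphereRadiusMm <- function(volumeCm3) (3 * volumeCm3 * 1000 / (4 * pi))^(1 / 3)

#' Voxels covered by a VOI sphere or ROI circle
#'
#' Discretizes a sphere VOI (all voxels whose centers lie within the
#' radius implied by the nominal volume, r = (3V / 4 pi)^(1/3)) or a
#' circle ROI (voxels of the single plane nearest the center, within the
#' radius implied by a one-voxel-plane-thick disc, r = sqrt(V / (pi t))).
#'
#' @param volume an \linkS4class{SUVVolume}.
#' @param voi a \linkS4class{VOISpec}.
#' @return Integer matrix, one row per member voxel (1-based i, j, k).
#' @examples
#' vol <- SUVVolume(array(1, c(20, 20, 20)), voxelSize = 1)
#' nrow(voxelsInVOI(vol, voiSpec("sinus", c(10, 10, 10), 0.5)))
#' @export
voxelsInVOI <- function(volume, voi) {
  stopifnot(is(volume, "SUVVolume"), is(voi, "VOISpec"))
  vs <- voxelSize(volume)
  dims <- dim(volume)
  extent <- dims * vs
  ctr <- voi@center
  if (voi@shape == "sphere") {
    r <- .sphereRadiusMm(voi@volumeCm3)
    if (any(ctr - r < 0) || any(ctr + r > extent))
      stop("VOI out of bounds")
    axes <- 1:3
  } else {
    ax <- voi@planeAxis
    axes <- setdiff(1:3, ax)
    t <- vs[ax]
    r <- sqrt(voi@volumeCm3 * 1000 / (pi * t))
    if (ctr[ax] < 0 || ctr[ax] > extent[ax] ||
        any(ctr[axes] - r < 0) || any(ctr[axes] + r > extent[axes]))
      stop("VOI out of bounds")
  }
  ## candidate index window, then exact center-distance test
  idxRange <- function(a, rad) {
    lo <- max(1L, floor((ctr[a] - rad) / vs[a] - 0.5) + 1L)
    hi <- min(dims[a], ceiling((ctr[a] + rad) / vs[a] + 0.5))
    lo:hi
  }
  if (voi@shape == "sphere") {
    ii <- idxRange(1, r); jj <- idxRange(2, r); kk <- idxRange(3, r)
    grid <- expand.grid(i = ii, j = jj, k = kk)
    d2 <- ((grid$i - 0.5) * vs[1] - ctr[1])^2 +
          ((grid$j - 0.5) * vs[2] - ctr[2])^2 +
          ((grid$k - 0.5) * vs[3] - ctr[3])^2
    keep <- d2 <= r^2
  } else {
    ax <- voi@planeAxis
    plane <- min(max(floor(ctr[ax] / vs[ax] + 0.5), 1L), dims[ax])
    rng <- list(idxRange(axes[1], r), idxRange(axes[2], r))
    grid2 <- expand.grid(a = rng[[1]], b = rng[[2]])
    grid <- data.frame(i = NA_integer_, j = NA_integer_, k = NA_integer_)
    grid <- grid[rep(1, nrow(grid2)), , drop = FALSE]
    grid[[axes[1]]] <- grid2$a
    grid[[axes[2]]] <- grid2$b
    grid[[ax]] <- plane
    names(grid) <- c("i", "j", "k")
    d2 <- ((grid2$a - 0.5) * vs[axes[1]] - ctr[axes[1]])^2 +
          ((grid2$b - 0.5) * vs[axes[2]] - ctr[axes[2]])^2
    keep <- d2 <= r^2
  }
  out <- as.matrix(grid[keep, , drop = FALSE])
  if (nrow(out) == 0L)
    stop("VOI smaller than one voxel")
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Mean or maximum SUV inside a VOI
#'
#' @param volume an \linkS4class{SUVVolume}.
#' @param voi a \linkS4class{VOISpec}.
#' @param statistic \code{"mean"} or \code{"max"}.
#' @return The SUV statistic over the member voxels.
#' @export
voiStatistic <- function(volume, voi, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  vox <- voxelsInVOI(volume, voi)
  vals <- suvValues(volume)[vox]
  if (statistic == "mean") mean(vals) else max(vals)
}

#' Point SUV at a world coordinate
#'
#' Reads the value of the voxel whose center is nearest the coordinate
#' (no interpolation); at a tie (coordinate exactly on a voxel face) the
#' lower index wins.
#'
#' @param volume an \linkS4class{SUVVolume}.
#' @param coordinate numeric length-3 world coordinates in mm.
#' @return The SUV of the nearest voxel.
#' @export
pointSUV <- function(volume, coordinate) {
  stopifnot(is(volume, "SUVVolume"), length(coordinate) == 3L)
  vs <- voxelSize(volume)
  dims <- dim(volume)
  if (any(coordinate < 0) || any(coordinate > dims * vs))
    stop("coordinate outside grid")
  idx <- pmin(pmax(floor(coordinate / vs + 0.5), 1L), dims)
  suvValues(volume)[matrix(as.integer(idx), nrow = 1)]
}

#' Measure a full reference panel on a dual-timepoint pair
#'
#' Applies identical VOI/ROI geometry to both timepoints and collects
#' brain mean/max, thalamus mean/max, plexus mean/max, artery max and
#' sinus max into a \linkS4class{ReferencePanel}.
#'
#' @param vol10,vol60 \linkS4class{SUVVolume}s of the early and late
#'   acquisition, on the same grid.
#' @param placements named list of \linkS4class{VOISpec}s covering
#'   \code{brain}, \code{thalamus}, \code{plexus}, \code{sinus},
#'   \code{artery}.
#' @param patientId identifier stored in the panel.
#' @return A \linkS4class{ReferencePanel}.
#' @examples
#' ph <- generatePhantom(defaultPhantomSpec(noiseSd = 0), medianUptakeModel())
#' p <- measureReferencePanel(ph$vol10, ph$vol60, defaultPlacements(ph$spec))
#' panelValue(p, "plexus", "max", "T10")
#' @export
measureReferencePanel <- function(vol10, vol60, placements,
                                  patientId = "P01") {
  needed <- c("brain", "thalamus", "plexus", "sinus", "artery")
  missing <- setdiff(needed, names(placements))
  if (length(missing))
    stop("missing placement for structure: ", paste(missing, collapse = ", "))
  vals <- stats::setNames(rep(NA_real_, length(.PANEL_ENTRIES)),
                          .PANEL_ENTRIES)
  vols <- list("10" = vol10, "60" = vol60)
  for (tp in names(vols)) {
    v <- vols[[tp]]
    for (s in c("brain", "thalamus", "plexus")) {
      vals[paste(s, "mean", tp, sep = "_")] <-
        voiStatistic(v, placements[[s]], "mean")
      vals[paste(s, "max", tp, sep = "_")] <-
        voiStatistic(v, placements[[s]], "max")
    }
    for (s in c("artery", "sinus")) {
      vals[paste(s, "max", tp, sep = "_")] <-
        voiStatistic(v, placements[[s]], "max")
    }
  }
  ReferencePanel(vals, patientId = patientId)
}

#' Euclidean dilation of a binary mask
#'
#' Grows the mask by a metric radius: the output contains every voxel
#' whose center lies within \code{radius} mm of a member voxel's center.
#' The output always contains the input; dilation by 0 is the identity.
#'
#' @param mask logical 3-D array, or a \linkS4class{DelineationMask}.
#' @param radius dilation radius in mm, non-negative.
#' @param voxelSize voxel edge lengths in mm (scalar recycled); ignored
#'   when \code{mask} is a \code{DelineationMask}.
#' @return Same type as the input mask.
#' @examples
#' m <- array(FALSE, c(21, 21, 21)); m[11, 11, 11] <- TRUE
#' sum(dilateMask(m, 5, voxelSize = 1))
#' @export
dilateMask <- function(mask, radius, voxelSize = c(1, 1, 1)) {
  if (is(mask, "DelineationMask")) {
    out <- dilateMask(mask@mask, radius, voxelSize(mask))
    prov <- mask@provenance
    prov$dilated_mm <- radius + if (is.null(prov$dilated_mm)) 0 else
      prov$dilated_mm
    return(new("DelineationMask", mask = out, voxelSize = voxelSize(mask),
               provenance = prov))
  }
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("radius must be a non-negative scalar")
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  ri <- floor(radius / voxelSize)
  if (all(ri == 0) || !any(mask)) return(mask)

  ## ball structuring element on the voxel lattice
  offs <- lapply(1:3, function(a) (-ri[a]):(ri[a]))
  d2 <- outer(outer((offs[[1]] * voxelSize[1])^2,
                    (offs[[2]] * voxelSize[2])^2, "+"),
              (offs[[3]] * voxelSize[3])^2, "+")
  kern <- d2 <= radius^2

  ## circular FFT convolution on a zero-padded grid, then crop
  n <- dim(mask)
  np <- n + 2 * ri
  P <- array(0, np)
  P[ri[1] + seq_len(n[1]), ri[2] + seq_len(n[2]), ri[3] + seq_len(n[3])] <-
    as.numeric(mask)
  K <- array(0, np)
  kidx <- lapply(1:3, function(a) as.integer((offs[[a]] %% np[a]) + 1L))
  K[kidx[[1]], kidx[[2]], kidx[[3]]] <- as.numeric(kern)
  conv <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) /
    prod(np)
  out <- conv[ri[1] + seq_len(n[1]), ri[2] + seq_len(n[2]),
              ri[3] + seq_len(n[3])] > 0.5
  array(out, dim = n)
}
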