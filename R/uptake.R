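#' Fit a lognormal distribution from a median and quartiles
#'
#' Closed-form moment-free calibration: the fitted lognormal has the given
#' median exactly (\code{mu = log(median)}) and its interquartile ratio
#' matches \code{upperQ/lowerQ}
#' (\code{sigma = log(upperQ/lowerQ) / (2 * qnorm(0.75))}).
#'
#' @param median,lowerQ,upperQ positive SUV quantiles with
#'   \code{lowerQ <= median <= upperQ}.
#' @return Named numeric vector \code{c(mu, sigma)} of the log-scale
#'   location and scale.
#' @examples
#' fitLognormalFromQuantiles(1.96, 1.39, 2.55)
#' @export
fitLognormalFromQuantiles <- function(median, lowerQ, upperQ) {
  if (any(!is.finite(c(median, lowerQ, upperQ))) ||
      any(c(median, lowerQ, upperQ) <= 0))
    stop("invalid quantiles: all inputs must be positive and finite")
  if (lowerQ > upperQ)
    stop("invalid quantiles: lowerQ must not exceed upperQ")
  if (median < lowerQ || median > upperQ)
    stop("invalid quantiles: median must lie between lowerQ and upperQ")
  c(mu = log(median),
    sigma = log(upperQ / lowerQ) / (2 * stats::qnorm(0.75)))
}

#' Default uptake model calibrated to the packaged summary tables
#'
#' Builds the tissue-wise SUV distribution model for the nine tissue
#' classes (brain, thalamus, plexus, sinus, artery, astrogliosis, G2, G3,
#' G4) at both timepoints from the packaged reference-structure and
#' per-grade fixtures. Brain and thalamus use their mean-SUV rows; plexus,
#' sinus and artery use their (max-statistic) rows.
#'
#' @param family sampling family: \code{"quantile"} (piecewise log-linear
#'   interpolation of the printed five-number summary; reproduces every
#'   printed quantile exactly and respects the printed bounds) or
#'   \code{"lognormal"} (truncated lognormal matched to median and IQR).
#' @param copulaRho Gaussian-copula correlation between the two timepoints
#'   of one sample, in [0, 1). Default 0.8.
#' @return An \linkS4class{UptakeModel}.
#' @examples
#' defaultUptakeModel()
#' @export
defaultUptakeModel <- function(family = c("quantile", "lognormal"),
                               copulaRho = 0.8) {
  family <- match.arg(family)
  ref <- referenceStructureTable()
  grade <- gradeUptakeTable()
  keep <- c("timepoint", "median", "lower_q", "upper_q", "min", "max")
  refRows <- ref[ref$structure %in% c("brain", "thalamus", "plexus",
                                      "sinus", "artery"), ]
  q <- rbind(
    cbind(data.frame(tissue = refRows$structure,
                     stringsAsFactors = FALSE), refRows[keep]),
    cbind(data.frame(tissue = grade$histology,
                     stringsAsFactors = FALSE), grade[keep]))
  rownames(q) <- NULL
  new("UptakeModel", quantiles = q, family = family, copulaRho = copulaRho)
}

#' Degenerate uptake model: every tissue fixed at its median
#'
#' Collapses each tissue's distribution to a point mass at the calibrated
#' median. Useful for noise-free phantoms with known voxel values.
#'
#' @inheritParams defaultUptakeModel
#' @return An \linkS4class{UptakeModel} whose draws are deterministic.
#' @export
medianUptakeModel <- function() {
  m <- defaultUptakeModel()
  q <- m@quantiles
  for (col in c("lower_q", "upper_q", "min", "max")) q[[col]] <- q$median
  new("UptakeModel", quantiles = q, family = "quantile", copulaRho = 0)
}

#' Kinetic factor of a tissue class
#'
#' Ratio of the late (60 min) to early (10 min) median SUV of a tissue.
#' Values above 1 mark rising uptake over time (astrogliosis, G2, brain,
#' thalamus), values below 1 falling uptake (plexus, sinus, G4).
#'
#' @param model an \linkS4class{UptakeModel}.
#' @param tissue tissue class name.
#' @return The unitless ratio median60 / median10.
#' @export
kineticFactor <- function(model, tissue) {
  m10 <- .uptakeRow(model, tissue, "10")$median
  m60 <- .uptakeRow(model, tissue, "60")$median
  m60 / m10
}

.uptakeRow <- function(model, tissue, timepoint) {
  q <- model@quantiles
  row <- q[q$tissue == tissue & q$timepoint == timepoint, ]
  if (nrow(row) != 1L)
    stop(sprintf("uptake model has no entry for tissue '%s' at timepoint %s",
                 tissue, timepoint))
  row
}

## Quantile function of one (tissue, timepoint) SUV distribution.
## "quantile" family: piecewise log-linear through the five-number summary,
## so min/LQ/median/UQ/max are reproduced exactly. "lognormal" family:
## inverse-CDF of the truncated lognormal fit.
.suvQuantile <- function(u, row, family) {
  knots <- c(row$min, row$lower_q, row$median, row$upper_q, row$max)
  if (diff(range(knots)) == 0) return(rep(knots[1], length(u)))
  if (family == "quantile") {
    exp(stats::approx(x = c(0, 0.25, 0.5, 0.75, 1), y = log(knots),
                      xout = u, rule = 2)$y)
  } else {
    par <- fitLognormalFromQuantiles(row$median, row$lower_q, row$upper_q)
    if (par["sigma"] == 0) return(rep(row$median, length(u)))
    pLo <- stats::plnorm(row$min, par["mu"], par["sigma"])
    pHi <- stats::plnorm(row$max, par["mu"], par["sigma"])
    stats::qlnorm(pLo + u * (pHi - pLo), par["mu"], par["sigma"])
  }
}

#' Draw coupled dual-timepoint SUVs for one tissue class
#'
#' Samples \code{n} (SUV10, SUV60) pairs from the tissue's calibrated
#' marginal distributions, coupled through a Gaussian copula with
#' correlation \code{copulaRho(model)}; identical seeds give identical
#' draws.
#'
#' @param model an \linkS4class{UptakeModel}.
#' @param tissue tissue class name.
#' @param n number of samples.
#' @param seed optional integer seed; the global RNG state is preserved.
#' @return A \code{data.frame} with columns \code{suv10}, \code{suv60}.
#' @examples
#' sampleUptake(defaultUptakeModel(), "G4", 5, seed = 1)
#' @export
sampleUptake <- function(model, tissue, n, seed = NULL) {
  stopifnot(n >= 0)
  draw <- function() {
    if (n == 0)
      return(data.frame(suv10 = numeric(0), suv60 = numeric(0)))
    u10 <- stats::runif(n)
    rho <- model@copulaRho
    z60 <- rho * stats::qnorm(u10) + sqrt(1 - rho^2) * stats::rnorm(n)
    u60 <- stats::pnorm(z60)
    data.frame(
      suv10 = .suvQuantile(u10, .uptakeRow(model, tissue, "10"),
                           model@family),
      suv60 = .suvQuantile(u60, .uptakeRow(model, tissue, "60"),
                           model@family))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
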