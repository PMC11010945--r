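# Independent brute-force oracles used across the suite.

# AUC as the fraction of positive-negative pairs where the positive
# scores higher, ties counted one half.
bruteForceAUC <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  total <- 0
  for (p in ps) total <- total + sum(p > ns) + 0.5 * sum(p == ns)
  total / (length(ps) * length(ns))
}

# Exhaustive Youden scan over midpoint candidates with the package's
# documented tie rule (max J, then max sensitivity, then lowest cutoff).
bruteForceYouden <- function(scores, pos) {
  us <- sort(unique(scores))
  if (length(us) < 2) return(NA_real_)
  thr <- (us[-1] + us[-length(us)]) / 2
  sens <- vapply(thr, function(c) mean(scores[pos] > c), 0)
  spec <- vapply(thr, function(c) mean(scores[!pos] <= c), 0)
  J <- sens + spec - 1
  cand <- which(J >= max(J) - 1e-12)
  cand <- cand[sens[cand] >= max(sens[cand]) - 1e-12]
  thr[min(cand)]
}

giniImpurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# Flat search over every feature and every midpoint between adjacent
# distinct values; returns the maximum achievable Gini decrease.
bruteForceBestGiniDecrease <- function(x, y) {
  g0 <- giniImpurity(y)
  n <- length(y)
  best <- -Inf
  for (f in seq_len(ncol(x))) {
    us <- sort(unique(x[[f]]))
    if (length(us) < 2) next
    for (thr in (us[-1] + us[-length(us)]) / 2) {
      left <- x[[f]] <= thr
      dec <- g0 - mean(left) * giniImpurity(y[left]) -
        mean(!left) * giniImpurity(y[!left])
      if (dec > best) best <- dec
    }
  }
  best
}

# A reference panel with every entry set explicitly (values chosen to be
# easy to hand-compute against).
flatPanel <- function(value = 1, patientId = "P01") {
  vals <- stats::setNames(rep(value, 16), fetquant:::.PANEL_ENTRIES)
  ReferencePanel(vals, patientId = patientId)
}

uniformVolume <- function(value, dims = c(10, 10, 10), voxelSize = 1,
                          timepoint = "T10") {
  SUVVolume(array(value, dim = dims), voxelSize = voxelSize,
            timepoint = timepoint)
}
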