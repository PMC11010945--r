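## Coerce labels to logical "is positive" (tumor). Accepts logical, 0/1
## numeric, or factor/character where "tumor"/"pathological" (or, failing
## that, the second sorted level) is the positive class.
.positiveLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- as.character(labels)
  lev <- sort(unique(lab))
  pos <- intersect(c("tumor", "pathological", "1", "TRUE"), lev)
  posLevel <- if (length(pos)) pos[1] else lev[length(lev)]
  lab == posLevel
}

## Mann-Whitney AUC with half-credit for ties, via midranks.
.aucMW <- function(scores, pos) {
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC analysis with AUC confidence interval and Youden cutoff
#'
#' Computes the full set of operating points over the candidate cutoffs
#' (midpoints between adjacent distinct scores; a sample is called
#' positive when its score exceeds the cutoff), the Mann--Whitney AUC
#' (ties counted one half), a 95\% confidence interval (DeLong by
#' default, percentile bootstrap as a cross-check), and the
#' Youden-optimal cutoff. Higher scores always point toward the positive
#' (tumor) class.
#'
#' @param scores numeric, finite.
#' @param labels class labels; see Details for accepted encodings
#'   (logical, 0/1, or \code{"tumor"}/\code{"astrogliosis"}).
#' @param ciMethod \code{"delong"} (default) or \code{"bootstrap"}.
#' @param bootN bootstrap replicates when \code{ciMethod = "bootstrap"}.
#' @return An \linkS4class{ROCResult}.
#' @examples
#' rocAnalysis(c(0.5, 0.6, 1.5, 1.6), c(0, 0, 1, 1))
#' @export
rocAnalysis <- function(scores, labels, ciMethod = c("delong", "bootstrap"),
                        bootN = 2000) {
  ciMethod <- match.arg(ciMethod)
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- .positiveLabels(labels)
  stopifnot(length(scores) == length(pos))
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) stop("degenerate labels")

  us <- sort(unique(scores))
  thr <- if (length(us) > 1) (us[-1] + us[-length(us)]) / 2 else numeric(0)
  sens <- vapply(thr, function(c) mean(scores[pos] > c), 0)
  spec <- vapply(thr, function(c) mean(scores[!pos] <= c), 0)

  aucVal <- .aucMW(scores, pos)
  ci <- c(NA_real_, NA_real_)
  if (length(us) > 1) {
    if (ciMethod == "delong") {
      ci <- tryCatch({
        r <- pROC::roc(response = pos, predictor = scores,
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
        suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
      }, error = function(e) c(aucVal, aucVal))
    } else {
      ci <- tryCatch({
        r <- pROC::roc(response = pos, predictor = scores,
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
        suppressWarnings(as.numeric(pROC::ci.auc(
          r, method = "bootstrap", boot.n = bootN,
          progress = "none"))[c(1, 3)])
      }, error = function(e) c(aucVal, aucVal))
    }
  } else {
    ci <- c(aucVal, aucVal)
  }
  ci[1] <- min(ci[1], aucVal)
  ci[2] <- max(ci[2], aucVal)

  res <- new("ROCResult", thresholds = thr, sensitivity = sens,
             specificity = spec, auc = aucVal, ciLow = ci[1], ciHigh = ci[2],
             ciMethod = ciMethod, youden = NA_real_,
             nPos = as.integer(nPos), nNeg = as.integer(nNeg))
  res@youden <- youdenOptimalCutoff(res)
  res
}

#' Youden-optimal cutoff of an ROC analysis
#'
#' Scans the candidate cutoffs (midpoints between adjacent distinct
#' scores) for the maximum of J = sensitivity + specificity - 1; ties are
#' broken toward higher sensitivity, then toward the lower cutoff.
#'
#' @param roc an \linkS4class{ROCResult}.
#' @return The optimal cutoff (NA when the scores admit no cutoff).
#' @export
youdenOptimalCutoff <- function(roc) {
  stopifnot(is(roc, "ROCResult"))
  if (length(roc@thresholds) == 0L) return(NA_real_)
  J <- roc@sensitivity + roc@specificity - 1
  cand <- which(J >= max(J) - 1e-12)
  cand <- cand[roc@sensitivity[cand] >=
                 max(roc@sensitivity[cand]) - 1e-12]
  roc@thresholds[min(cand)]
}

#' Confusion-matrix metrics
#'
#' Counts true/false positives/negatives of a binary prediction against
#' the truth and derives sensitivity, specificity, PPV and NPV by exact
#' division.
#'
#' @param labels true labels.
#' @param predictions predicted labels, same encoding and length.
#' @return A list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv}
#'   (rates are \code{NaN} when their denominator is empty).
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusionMetrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  truth <- .positiveLabels(labels)
  pred <- .positiveLabels(predictions)
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred)
  fn <- sum(truth & !pred)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn))
}

#' Predictive values from rates and class sizes
#'
#' Bayes-consistent positive and negative predictive values implied by a
#' sensitivity, a specificity and the two class sizes:
#' PPV = sens n+ / (sens n+ + (1 - spec) n-) and
#' NPV = spec n- / (spec n- + (1 - sens) n+).
#'
#' @param sensitivity,specificity rates in [0, 1].
#' @param nPos,nNeg positive class sizes.
#' @return A list with \code{ppv} and \code{npv}.
#' @examples
#' metricsFromRates(0.95, 0.58, 230, 54)
#' @export
metricsFromRates <- function(sensitivity, specificity, nPos, nNeg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 ||
      specificity > 1)
    stop("rates must lie in [0, 1]")
  if (nPos <= 0 || nNeg <= 0) stop("class sizes must be positive")
  ppvDen <- sensitivity * nPos + (1 - specificity) * nNeg
  npvDen <- specificity * nNeg + (1 - sensitivity) * nPos
  if (ppvDen == 0 || npvDen == 0) stop("undefined predictive value")
  list(ppv = sensitivity * nPos / ppvDen,
       npv = specificity * nNeg / npvDen)
}

#' Paired comparison of two ROC curves (DeLong test)
#'
#' Compares the AUCs of two score vectors measured on the same samples.
#'
#' @param scoresA,scoresB numeric score vectors over the same samples.
#' @param labels class labels.
#' @return A list with \code{aucA}, \code{aucB}, \code{aucDiff} and
#'   \code{pValue} (two-sided; 1 when the scores are identical).
#' @examples
#' compareROCPaired(c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 0, 1, 1))
#' @export
compareROCPaired <- function(scoresA, scoresB, labels) {
  pos <- .positiveLabels(labels)
  if (length(scoresA) != length(pos) || length(scoresB) != length(pos))
    stop("scores and labels must have equal length")
  if (sum(pos) == 0 || sum(!pos) == 0) stop("degenerate labels")
  aucA <- .aucMW(scoresA, pos)
  aucB <- .aucMW(scoresB, pos)
  d <- aucA - aucB
  if (isTRUE(all.equal(scoresA, scoresB)))
    return(list(aucA = aucA, aucB = aucB, aucDiff = 0, pValue = 1))
  p <- tryCatch({
    rA <- pROC::roc(response = pos, predictor = scoresA,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    rB <- pROC::roc(response = pos, predictor = scoresB,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    suppressWarnings(
      pROC::roc.test(rA, rB, paired = TRUE, method = "delong")$p.value)
  }, error = function(e) NA_real_)
  if (!is.finite(p)) p <- if (abs(d) < 1e-12) 1 else NA_real_
  list(aucA = aucA, aucB = aucB, aucDiff = d, pValue = p)
}

#' Trajectory-by-histology contingency summary
#'
#' Cross-tabulates biopsy samples by histology (rows) and trajectory
#' class (columns), with an overall column, and integer percentages per
#' column (half-up rounding, matching the printed layout).
#'
#' @param samples \code{data.frame} with \code{trajectory} and
#'   \code{histology} columns.
#' @return A list with \code{counts} and \code{percent} matrices
#'   (histology x c(Overall, trajectories)), \code{nTotal} and
#'   \code{nTumor}.
#' @examples
#' contingencySummary(cohortSamples())$nTotal
#' @export
contingencySummary <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0,
            all(c("trajectory", "histology") %in% names(samples)))
  hist <- factor(samples$histology,
                 levels = intersect(.HISTOLOGY,
                                    unique(samples$histology)))
  traj <- factor(samples$trajectory,
                 levels = intersect(.TRAJECTORIES,
                                    unique(samples$trajectory)))
  tab <- table(hist, traj)
  counts <- cbind(Overall = rowSums(tab), unclass(tab))
  halfUp <- function(x) floor(x + 0.5)
  percent <- counts
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    percent[, j] <- if (tot > 0) halfUp(100 * counts[, j] / tot) else 0
  }
  list(counts = counts, percent = percent,
       nTotal = nrow(samples),
       nTumor = sum(samples$histology %in% .TUMOR_TISSUES))
}
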