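#' CART fitting parameters
#'
#' @param minNodeFraction direct stop rule: a node is not split when it
#'   holds less than this fraction of the training rows (default 0.05).
#' @param maxDepth maximum tree depth (root = 0; default 10).
#' @param cvFolds number of cross-validation folds (default 10; at least
#'   2).
#' @param seed optional integer seed for the fold assignment.
#' @return A list of validated parameters.
#' @export
cartParams <- function(minNodeFraction = 0.05, maxDepth = 10L,
                       cvFolds = 10L, seed = NULL) {
  if (minNodeFraction <= 0 || minNodeFraction >= 1)
    stop("'minNodeFraction' must lie in (0, 1)")
  if (cvFolds < 2)
    stop("'cvFolds' must be at least 2")
  list(minNodeFraction = minNodeFraction, maxDepth = as.integer(maxDepth),
       cvFolds = as.integer(cvFolds), seed = seed)
}

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

## Exhaustive Gini split search for one node: every feature, every
## midpoint between adjacent distinct sorted values. Ties break toward
## the earlier feature column, then the lower threshold.
.bestSplit <- function(xm, yInt, K) {
  n <- length(yInt)
  parentCounts <- tabulate(yInt, K)
  gParent <- .gini(parentCounts)
  best <- NULL
  for (f in seq_len(ncol(xm))) {
    xv <- xm[, f]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- yInt[ord]
    ## cumulative class counts left of each cut position
    cum <- apply(outer(ys, seq_len(K), "=="), 2, cumsum)
    if (n == 1) cum <- matrix(cum, nrow = 1)
    cutAfter <- which(diff(xs) > 0)
    for (pos in cutAfter) {
      left <- cum[pos, ]
      right <- parentCounts - left
      nL <- pos
      nR <- n - pos
      dec <- gParent - (nL / n) * .gini(left) - (nR / n) * .gini(right)
      thr <- (xs[pos] + xs[pos + 1]) / 2
      ## features scanned in column order and thresholds ascending, so
      ## keeping only strict improvements breaks ties toward the earlier
      ## feature and the lower threshold
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(feature = f, threshold = thr, decrease = dec)
    }
  }
  best
}

.fisherNodeP <- function(inNode, yInt, K) {
  tab <- rbind(tabulate(yInt[inNode], K), tabulate(yInt[!inNode], K))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || nrow(tab) < 2 || any(rowSums(tab) == 0))
    return(1)
  stats::fisher.test(tab)$p.value
}

.growCart <- function(xm, yInt, K, params) {
  n <- nrow(xm)
  minN <- max(1L, ceiling(params$minNodeFraction * n))
  nodes <- list()
  counts <- list()
  addNode <- function(rows, depth) {
    id <- length(nodes) + 1L
    cnt <- tabulate(yInt[rows], K)
    pred <- which.max(cnt)
    pv <- .fisherNodeP(seq_len(n) %in% rows, yInt, K)
    rec <- data.frame(id = id, depth = depth, n = length(rows),
                      feature = NA_character_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_,
                      prediction = pred, p_value = pv, is_leaf = TRUE,
                      stringsAsFactors = FALSE)
    nodes[[id]] <<- rec
    counts[[id]] <<- cnt
    pure <- sum(cnt > 0) <= 1
    if (!pure && length(rows) >= minN && depth < params$maxDepth) {
      sp <- .bestSplit(xm[rows, , drop = FALSE], yInt[rows], K)
      if (!is.null(sp) && sp$decrease > 1e-12) {
        goLeft <- xm[rows, sp$feature] <= sp$threshold
        leftId <- addNode(rows[goLeft], depth + 1L)
        rightId <- addNode(rows[!goLeft], depth + 1L)
        nodes[[id]]$feature <<- colnames(xm)[sp$feature]
        nodes[[id]]$threshold <<- sp$threshold
        nodes[[id]]$left <<- leftId
        nodes[[id]]$right <<- rightId
        nodes[[id]]$is_leaf <<- FALSE
      }
    }
    id
  }
  addNode(seq_len(n), 0L)
  list(nodes = do.call(rbind, nodes), counts = do.call(rbind, counts))
}

.routeCart <- function(nodes, xm) {
  n <- nrow(xm)
  pred <- integer(n)
  for (i in seq_len(n)) {
    id <- 1L
    while (!nodes$is_leaf[id]) {
      f <- nodes$feature[id]
      v <- xm[i, f]
      if (is.na(v)) stop(sprintf("missing split feature '%s'", f))
      id <- if (v <= nodes$threshold[id]) nodes$left[id] else
        nodes$right[id]
    }
    pred[i] <- nodes$prediction[id]
  }
  pred
}

#' Fit a classification tree (C&RT with Gini splitting)
#'
#' Binary recursive partitioning: at each node the split maximizing the
#' Gini impurity decrease over all features and all midpoints between
#' adjacent distinct values is chosen; growth stops when a node is pure,
#' falls below the direct-stop minimum node fraction, reaches the maximum
#' depth, or no split reduces impurity. Each node carries a Fisher-exact
#' p-value for class membership inside versus outside the node
#' (descriptive; splits are selected by Gini decrease only). The
#' resubstitution misclassification cost and the V-fold cross-validation
#' cost with its standard error are reported so over-training can be
#' judged by comparing the two.
#'
#' @param x \code{data.frame} or matrix of numeric features, no missing
#'   values.
#' @param y class labels (factor or character); a single-class input
#'   yields a degenerate single-leaf tree.
#' @param params see \code{\link{cartParams}}.
#' @return A \linkS4class{CartTree}.
#' @examples
#' fit <- fitCart(data.frame(x = c(1, 2, 4, 5)),
#'                c("a", "a", "b", "b"),
#'                cartParams(cvFolds = 2, seed = 1))
#' fit
#' @export
fitCart <- function(x, y, params = cartParams()) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) stop("empty input")
  if (any(!vapply(x, is.numeric, TRUE)))
    stop("all features must be numeric")
  xm <- as.matrix(x)
  if (any(is.na(xm)) || any(is.na(y)))
    stop("missing values are not allowed (apply complete-case filtering)")
  y <- factor(y)
  classLevels <- levels(y)
  K <- length(classLevels)
  yInt <- as.integer(y)
  n <- nrow(xm)

  grown <- .growCart(xm, yInt, K, params)
  resub <- mean(.routeCart(grown$nodes, xm) != yInt)

  cv <- NA_real_
  cvSE <- NA_real_
  if (n >= params$cvFolds && K >= 2) {
    runCV <- function() {
      folds <- sample(rep_len(seq_len(params$cvFolds), n))
      loss <- numeric(n)
      for (v in seq_len(params$cvFolds)) {
        tr <- folds != v
        if (length(unique(yInt[tr])) < 1 || !any(tr)) next
        g <- .growCart(xm[tr, , drop = FALSE], yInt[tr], K, params)
        loss[!tr] <- .routeCart(g$nodes, xm[!tr, , drop = FALSE]) !=
          yInt[!tr]
      }
      loss
    }
    loss <- if (is.null(params$seed)) runCV() else
      withr::with_seed(params$seed, runCV())
    cv <- mean(loss)
    cvSE <- stats::sd(loss) / sqrt(n)
  }

  nodes <- grown$nodes
  nodes$prediction <- classLevels[nodes$prediction]
  new("CartTree", nodes = nodes, counts = grown$counts,
      classLevels = classLevels,
      costs = list(resubstitution = resub, cv = cv, cvSE = cvSE),
      params = params)
}

#' Predict with a fitted CART tree
#'
#' Routes each row down the tree (values less than or equal to a node's
#' threshold go left) and returns the leaf's majority class.
#'
#' @param tree a \linkS4class{CartTree}.
#' @param newdata \code{data.frame} holding every split feature.
#' @return Character vector of predicted class labels.
#' @export
predictCart <- function(tree, newdata) {
  stopifnot(is(tree, "CartTree"))
  newdata <- as.data.frame(newdata)
  used <- unique(stats::na.omit(tree@nodes$feature))
  missing <- setdiff(used, names(newdata))
  if (length(missing))
    stop("missing split feature: ", paste(missing, collapse = ", "))
  if (nrow(newdata) == 0L) return(character(0))
  xm <- as.matrix(newdata[used])
  nodes <- tree@nodes
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    id <- 1L
    while (!nodes$is_leaf[id]) {
      v <- xm[i, nodes$feature[id]]
      if (is.na(v)) stop(sprintf("missing split feature '%s'",
                                 nodes$feature[id]))
      id <- if (v <= nodes$threshold[id]) nodes$left[id] else
        nodes$right[id]
    }
    out[i] <- nodes$prediction[id]
  }
  out
}

#' Per-node training summary of a CartTree
#'
#' @param tree a \linkS4class{CartTree}.
#' @return A \code{data.frame} of node records joined with per-class
#'   training counts.
#' @export
cartNodes <- function(tree) {
  stopifnot(is(tree, "CartTree"))
  cnt <- tree@counts
  colnames(cnt) <- paste0("n_", tree@classLevels)
  cbind(tree@nodes, as.data.frame(cnt))
}
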