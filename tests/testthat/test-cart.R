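test_that("a separable 1-D problem splits at the midpoint", {
  fit <- fitCart(data.frame(x = c(1, 2, 4, 5)),
                 c("a", "a", "b", "b"),
                 cartParams(cvFolds = 2, seed = 1))
  root <- fit@nodes[1, ]
  expect_identical(root$feature, "x")
  expect_equal(root$threshold, 3)
  expect_equal(fit@costs$resubstitution, 0)
  expect_identical(predictCart(fit, data.frame(x = 2)), "a")
  expect_identical(predictCart(fit, data.frame(x = 4.5)), "b")
})

test_that("degenerate inputs are handled as documented", {
  pure <- fitCart(data.frame(x = 1:6), rep("a", 6),
                  cartParams(cvFolds = 2, seed = 1))
  expect_identical(nrow(pure@nodes), 1L)
  expect_equal(pure@costs$resubstitution, 0)
  expect_identical(unique(predictCart(pure, data.frame(x = c(-1, 99)))),
                   "a")
  expect_error(fitCart(data.frame(x = numeric(0)), character(0)),
               "empty input")
  expect_error(fitCart(data.frame(x = c(1, NA)), c("a", "b")), "missing")
  expect_error(cartParams(minNodeFraction = 0))
  expect_error(cartParams(cvFolds = 1))
})

test_that("the chosen split maximizes Gini decrease (brute-force oracle)", {
  for (rep in 1:15) {
    set.seed(rep + 300)
    n <- sample(20:200, 1)
    x <- data.frame(f1 = round(runif(n, 0, 3), 2),
                    f2 = round(rnorm(n), 2),
                    f3 = sample(0:4, n, replace = TRUE) / 2)
    y <- ifelse(x$f1 + 0.5 * x$f2 + rnorm(n, 0, 0.7) > 1.5, "t", "a")
    if (length(unique(y)) < 2) next
    fit <- fitCart(x, y, cartParams(maxDepth = 1, cvFolds = 2, seed = 1))
    root <- fit@nodes[1, ]
    oracle <- bruteForceBestGiniDecrease(x, y)
    if (is.na(root$feature)) {
      expect_lte(oracle, 1e-12)
    } else {
      left <- x[[root$feature]] <= root$threshold
      g0 <- giniImpurity(y)
      achieved <- g0 - mean(left) * giniImpurity(y[left]) -
        mean(!left) * giniImpurity(y[!left])
      expect_equal(achieved, oracle, tolerance = 1e-12)
    }
  }
})

test_that("routing is deterministic and ignores irrelevant features", {
  set.seed(5)
  x <- data.frame(a = runif(60), b = runif(60))
  y <- ifelse(x$a > 0.5, "t", "n")
  fit <- fitCart(x, y, cartParams(cvFolds = 5, seed = 2))
  new <- data.frame(a = c(0.2, 0.8), b = c(0.1, 0.9))
  p1 <- predictCart(fit, new)
  new$b <- rev(new$b) * 100  # b never used by the tree
  expect_identical(predictCart(fit, new), p1)
  expect_error(predictCart(fit, data.frame(b = 1)), "missing split feature")
})

test_that("cross-validation cost is reported with its standard error", {
  set.seed(6)
  x <- data.frame(u = runif(80), v = runif(80))
  y <- sample(c("a", "b"), 80, replace = TRUE)  # labels independent of x
  fit <- fitCart(x, y, cartParams(cvFolds = 5, seed = 3))
  expect_true(is.finite(fit@costs$cv))
  expect_true(is.finite(fit@costs$cvSE))
  expect_gte(fit@costs$cv, 0)
  expect_lte(fit@costs$cv, 1)
  # per-node Fisher p-values are valid probabilities
  expect_true(all(fit@nodes$p_value >= 0 & fit@nodes$p_value <= 1))
  # node counts route every training row to exactly one leaf
  leaves <- fit@nodes$is_leaf
  expect_identical(sum(fit@counts[leaves, ]), 80L)
})

test_that("predictions agree with rpart on a cleanly separable problem", {
  skip_if_not_installed("rpart")
  set.seed(7)
  n <- 120
  x <- data.frame(f = c(runif(n / 2, 0, 1), runif(n / 2, 2, 3)))
  y <- rep(c("low", "high"), each = n / 2)
  fit <- fitCart(x, y, cartParams(cvFolds = 5, seed = 1))
  rp <- rpart::rpart(factor(y) ~ f, data = x, method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0))
  new <- data.frame(f = seq(0, 3, by = 0.25))
  expect_identical(predictCart(fit, new),
                   as.character(predict(rp, new, type = "class")))
})
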