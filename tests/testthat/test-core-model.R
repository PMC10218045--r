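test_that("soft thresholding shrinks toward zero and keeps signs", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.5, 0.2), -0.3)
  expect_equal(soft_threshold(0.1, 0.2), 0)
  expect_equal(soft_threshold(c(1, -2, 0.5), 1), c(0, -1, 0))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("quantile threshold leaves about (1 - q) * m survivors", {
  w <- c(1, -2, 3, -4, 5, -6, 7, -8, 9, -10) / 10
  lam <- lambda_from_quantile(w, 0.9)
  # brute-force survivor count under the type-7 quantile of |w|
  survivors <- sum(abs(w) - lam > 0)
  expect_equal(survivors, 1)
  expect_equal(which(soft_threshold(w, lam) != 0), 10)

  # quantile 0 drops nothing
  expect_equal(lambda_from_quantile(w, 0), 0)
  expect_true(all(soft_threshold(w, lambda_from_quantile(w, 0)) != 0))

  expect_error(lambda_from_quantile(w, 1), "\\[0, 1\\)")
  expect_error(lambda_from_quantile(w, -0.1), "\\[0, 1\\)")
  expect_error(lambda_from_quantile(numeric(0), 0.5), "non-empty")
})

test_that("a constant-magnitude weight vector is rejected, not zeroed", {
  set.seed(11)
  u <- rnorm(12)
  X <- cbind(u + rnorm(12, sd = 0.1))
  X <- cbind(X, X[, 1])  # identical columns -> |w| constant
  inp <- centered_inputs(X, rep(0:1, 6))
  expect_error(fit_component(list(scale(inp$X)), inp$Y, quantiles = 0.5),
               "constant magnitude|all weights zero")
})

test_that("with quantile 0 the weight equals the classical PLS1 weight", {
  set.seed(12)
  X <- matrix(rnorm(30 * 8), 30)
  inp <- centered_inputs(X, rep(0:1, 15))
  cf <- fit_component(list(inp$X), inp$Y, quantiles = 0)
  w_closed <- drop(crossprod(inp$X, drop(inp$Y)))
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  s <- sign(w_closed[which.max(abs(w_closed))])
  expect_equal(cf$block_weights[[1]], s * w_closed,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("weights match an exhaustive covariance grid search (2 features)", {
  set.seed(13)
  X <- matrix(rnorm(25 * 2), 25)
  inp <- centered_inputs(X, rep(0:1, length.out = 25))
  cf <- fit_component(list(inp$X), inp$Y, quantiles = 0)
  u <- drop(inp$Y)
  cc <- drop(crossprod(inp$X, u))
  theta <- seq(0, 2 * pi, length.out = 1e6)
  obj <- cos(theta) * cc[1] + sin(theta) * cc[2]
  best <- theta[which.max(obj)]
  w_grid <- c(cos(best), sin(best))
  s <- sign(w_grid[which.max(abs(w_grid))])
  expect_equal(unname(cf$block_weights[[1]]), s * w_grid, tolerance = 1e-4)
})

test_that("the generating feature attracts all weight at high quantile", {
  set.seed(14)
  X <- matrix(rnorm(40 * 6), 40)
  y01 <- as.integer(X[, 1] > 0)
  inp <- centered_inputs(X, y01)
  cf <- fit_component(list(inp$X), inp$Y, quantiles = 5 / 6)
  expect_equal(unname(cf$support[[1]]), 1)
  expect_equal(abs(unname(cf$block_weights[[1]][1])), 1)
})

test_that("a block nearly orthogonal to u gets near-zero super weight", {
  set.seed(15)
  n <- 30
  y01 <- rep(0:1, 15)
  u <- y01 - mean(y01)
  x1 <- u + rnorm(n, sd = 0.1)
  raw <- rnorm(n)
  x2 <- raw - u * sum(raw * u) / sum(u^2) + 1e-8 * u  # ~orthogonal to u
  cf <- fit_component(list(matrix(x1), matrix(x2)),
                      matrix(u), quantiles = c(0, 0))
  expect_lt(abs(cf$super_weight[2]), 1e-6 * abs(cf$super_weight[1]))
})

test_that("deflation removes the super score from X and Y", {
  set.seed(16)
  x <- random_multiblock(25, c(10, 4))
  y <- balanced_binary(25)
  pp <- weighted_center_scale(x, y)
  cf <- fit_component(pp$x$blocks, pp$y, quantiles = c(0.3, 0.3))
  d <- deflate(pp$x$blocks, pp$y, cf$t_super)
  for (b in 1:2)
    expect_lt(max(abs(crossprod(d$blocks[[b]], cf$t_super))), 1e-8)
  expect_lt(max(abs(crossprod(d$Y, cf$t_super))), 1e-8)

  # rank-1 X spanned by t_super deflates to zero
  t1 <- cf$t_super
  Xr1 <- tcrossprod(t1, rnorm(5))
  dr <- deflate(list(Xr1), pp$y, t1)
  expect_lt(max(abs(dr$blocks[[1]])), 1e-10)

  expect_error(deflate(pp$x$blocks, pp$y, rep(0, 25)), "zero-norm")
})

test_that("fitted components satisfy the unit-norm and sparsity contracts", {
  set.seed(17)
  x <- random_multiblock(30, c(15, 6))
  y <- balanced_binary(30)
  qt <- matrix(c(0.6, 0.5, 0.8, 0.4), 2, 2, byrow = TRUE)
  fit <- asmbplsda(x, y, qt)
  for (j in 1:2) {
    cm <- fit$components[[j]]
    for (b in 1:2) {
      expect_equal(sum(cm$block_weights[[b]]^2), 1, tolerance = 1e-10)
      expect_lte(sum(cm$block_weights[[b]] != 0),
                 ceiling((1 - qt[j, b]) * block_sizes(x)[b]))
    }
    expect_equal(sum(cm$super_weight^2), 1, tolerance = 1e-10)
  }
  s <- fit$super_scores
  expect_lt(abs(sum(s[, 1] * s[, 2])) /
              (sqrt(sum(s[, 1]^2)) * sqrt(sum(s[, 2]^2))), 1e-8)
})

test_that("refitting on the deflated residual reproduces component 2", {
  set.seed(18)
  x <- random_multiblock(24, c(8, 5))
  y <- balanced_binary(24)
  qt <- matrix(0.4, 2, 2)
  fit <- asmbplsda(x, y, qt)
  pp <- weighted_center_scale(x, y)
  cf1 <- fit_component(pp$x$blocks, pp$y, qt[1, ])
  d <- deflate(pp$x$blocks, pp$y, cf1$t_super)
  cf2 <- fit_component(d$blocks, d$Y, qt[2, ])
  for (b in 1:2)
    expect_equal(cf2$block_weights[[b]],
                 fit$components[[2]]$block_weights[[b]], tolerance = 1e-12)
  expect_equal(cf2$t_super, unname(fit$super_scores[, 2]),
               tolerance = 1e-12)
})

test_that("selected features are the union of component supports", {
  set.seed(19)
  x <- random_multiblock(30, c(12, 5))
  fit <- asmbplsda(x, balanced_binary(30), matrix(0.5, 2, 2))
  for (b in 1:2) {
    sup <- union(names(fit$components[[1]]$block_weights[[b]])[
                   fit$components[[1]]$support[[b]]],
                 names(fit$components[[2]]$block_weights[[b]])[
                   fit$components[[2]]$support[[b]]])
    expect_setequal(selected_features(fit)[[b]], sup)
  }
})

test_that("permuting features within a block permutes weights, scores fixed", {
  set.seed(20)
  x <- random_multiblock(25, c(9, 4))
  y <- balanced_binary(25)
  qt <- matrix(c(0.5, 0.3), 1, 2)
  fit <- asmbplsda(x, y, qt, n_components = 1)
  perm <- sample(9)
  xp <- multiblock(list(block1 = x$blocks[[1]][, perm],
                        block2 = x$blocks[[2]]))
  fitp <- asmbplsda(xp, y, qt, n_components = 1)
  expect_equal(unname(fitp$components[[1]]$block_weights[[1]]),
               unname(fit$components[[1]]$block_weights[[1]][perm]),
               tolerance = 1e-12)
  expect_equal(fitp$super_scores, fit$super_scores, tolerance = 1e-12)
})

test_that("transform is the identity on training super scores", {
  set.seed(21)
  x <- random_multiblock(20, c(7, 3))
  fit <- asmbplsda(x, balanced_binary(20), matrix(0.4, 2, 2))
  expect_equal(super_scores(fit, x), fit$super_scores, tolerance = 1e-12)
  # a single sample equal to a training sample gives the same score row
  one <- asmbplsda:::mb_rows(x, 3)
  expect_equal(drop(super_scores(fit, one)),
               fit$super_scores[3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Y-estimates are additive in components and exact on rank-1 data", {
  set.seed(22)
  x <- random_multiblock(20, c(7, 3))
  y <- balanced_binary(20)
  fit <- asmbplsda(x, y, matrix(0.4, 2, 2))
  # empty sum: zero centered estimates
  e0 <- predict_y(fit, x, n_components = 0, shift = FALSE)
  expect_true(all(e0 == 0))
  # adding component 2 changes estimates by exactly t_super %*% y_loading'
  e1 <- predict_y(fit, x, n_components = 1, shift = FALSE)
  e2 <- predict_y(fit, x, n_components = 2, shift = FALSE)
  expect_equal(e2 - e1,
               tcrossprod(fit$super_scores[, 2],
                          fit$components[[2]]$y_loading),
               tolerance = 1e-12, ignore_attr = TRUE)

  # noiseless rank-1 X with Y proportional to the generating score:
  # one component reconstructs the centered Y exactly
  u0 <- rep(c(-0.5, 0.5), each = 10)
  v <- runif(6, 0.5, 2)
  X <- tcrossprod(u0, v) + 0
  xr <- multiblock(list(b = X))
  yr <- factor(rep(0:1, each = 10))
  fr <- asmbplsda(xr, yr, matrix(0, 1, 1), n_components = 1)
  res <- predict_y(fr, xr, n_components = 1, shift = FALSE)
  Yc <- u0  # centered dummy outcome
  expect_equal(drop(res), Yc, tolerance = 1e-8, ignore_attr = TRUE)
})
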