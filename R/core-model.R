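#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - lambda, 0)`, applied elementwise. This is the
#' shrinkage used to zero small block weights and so select features.
#'
#' @param w Numeric vector of weights.
#' @param lam Non-negative threshold.
#' @return Numeric vector of the same length as `w`.
#' @export
#' @examples
#' soft_threshold(c(0.5, -0.5, 0.1), 0.2)
soft_threshold <- function(w, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("'lam' must be a single non-negative number", call. = FALSE)
  sign(w) * pmax(abs(w) - lam, 0)
}

#' Threshold from a weight quantile
#'
#' Returns the empirical (type-7) quantile of the absolute weights, used as
#' the soft-threshold lambda. The quantile is the approximate fraction of
#' features dropped in the block, so roughly `(1 - quantile) * m` entries
#' survive thresholding. A quantile of 0 drops nothing and returns 0.
#'
#' @param w Numeric weight vector (non-empty).
#' @param quantile Scalar in `[0, 1)`.
#' @return The threshold lambda.
#' @export
lambda_from_quantile <- function(w, quantile) {
  if (length(w) == 0L) stop("'w' must be non-empty", call. = FALSE)
  if (!is.numeric(quantile) || length(quantile) != 1L || is.na(quantile) ||
      quantile < 0 || quantile >= 1)
    stop("'quantile' must be in [0, 1)", call. = FALSE)
  if (quantile == 0) return(0)
  stats::quantile(abs(w), probs = quantile, type = 7, names = FALSE)
}

unit_norm <- function(v, what = "vector") {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps)
    stop("cannot normalize zero ", what, call. = FALSE)
  v / nv
}

#' Extract one sparse PLS component
#'
#' One round of the iterative weight algorithm on (already deflated and
#' preprocessed) data: the outcome score `u` starts at the first column of
#' `Y`; block weights `X_b' u` are normalized, soft-thresholded at the
#' per-block quantile of their absolute values and renormalized on the
#' surviving support; block scores `t_b = X_b w_b / sqrt(m_b)` are combined
#' through the super weight into the super score, and the outcome weight `q`
#' and `u = Y q` are updated until the super score converges. Signs are fixed
#' so each weight vector's largest-magnitude entry is positive.
#'
#' @param blocks List of centered/scaled block matrices (deflated as needed).
#' @param Y Centered outcome matrix.
#' @param quantiles Numeric vector, one sparsity quantile in `[0, 1)` per
#'   block.
#' @param tol Relative convergence tolerance on the super score.
#' @param max_iter Maximum number of weight-update iterations.
#' @return A list of class `"component_fit"`: `block_weights` (unit-norm
#'   sparse vectors), `super_weight`, `q`, `t_blocks`, `t_super`, `u`,
#'   `lambdas`, `support` (indices of non-zero weights per block) and
#'   `iterations`.
#' @export
fit_component <- function(blocks, Y, quantiles, tol = 1e-8, max_iter = 500L) {
  B <- length(blocks)
  if (length(quantiles) != B)
    stop("need one quantile per block", call. = FALSE)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  m <- vapply(blocks, ncol, integer(1))
  u <- Y[, 1L]
  W <- vector("list", B)
  lambdas <- numeric(B)
  Tmat <- matrix(0, n, B)
  t_super_old <- NULL
  converged <- FALSE
  delta <- NA_real_
  for (iter in seq_len(max_iter)) {
    for (b in seq_len(B)) {
      w <- drop(crossprod(blocks[[b]], u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps)
        stop("block ", b, ": weights are all zero (block uncorrelated with ",
             "the outcome score)", call. = FALSE)
      w <- w / nw
      lam <- lambda_from_quantile(w, quantiles[b])
      w <- soft_threshold(w, lam)
      if (all(w == 0))
        stop("block ", b, ": all weights zero after soft-thresholding at ",
             "quantile ", quantiles[b],
             " (weights may have constant magnitude)", call. = FALSE)
      W[[b]] <- w / sqrt(sum(w^2))
      lambdas[b] <- lam
      Tmat[, b] <- blocks[[b]] %*% W[[b]] / sqrt(m[b])
    }
    ws <- unit_norm(drop(crossprod(Tmat, u)), "super weight")
    t_super <- drop(Tmat %*% ws)
    q <- unit_norm(drop(crossprod(Y, t_super)), "outcome weight")
    u <- drop(Y %*% q)
    if (!is.null(t_super_old)) {
      delta <- sqrt(sum((t_super - t_super_old)^2)) /
        max(sqrt(sum(t_super_old^2)), .Machine$double.eps)
      if (delta < tol) { converged <- TRUE; break }
    }
    t_super_old <- t_super
  }
  if (!converged && max_iter > 1L)
    stop("component did not converge after ", max_iter,
         " iterations (last relative change ", signif(delta, 3), ")",
         call. = FALSE)
  # sign convention: largest-|w| entry positive, per block and for the
  # super weight; compensating flips leave t_super q' unchanged
  for (b in seq_len(B)) {
    s <- sign(W[[b]][which.max(abs(W[[b]]))])
    if (s < 0) {
      W[[b]] <- -W[[b]]
      ws[b] <- -ws[b]
      Tmat[, b] <- -Tmat[, b]
    }
  }
  s <- sign(ws[which.max(abs(ws))])
  if (s < 0) {
    ws <- -ws
    q <- -q
    u <- -u
  }
  t_super <- drop(Tmat %*% ws)
  for (b in seq_len(B)) names(W[[b]]) <- colnames(blocks[[b]])
  structure(list(
    block_weights = W,
    super_weight = ws,
    q = q,
    t_blocks = Tmat,
    t_super = t_super,
    u = u,
    lambdas = lambdas,
    quantiles = quantiles,
    support = lapply(W, function(w) which(w != 0)),
    iterations = iter
  ), class = "component_fit")
}

#' Deflate the working matrices after a component
#'
#' Removes the rank-one part of each block and of the outcome explained by
#' the super score: `X_b <- X_b - t p_b'` with regression loading
#' `p_b = X_b' t / (t' t)`, and likewise `Y <- Y - t g'` with
#' `g = Y' t / (t' t)`. `g` (the Y regression loading) is what prediction
#' accumulates.
#'
#' @param blocks List of block matrices the component was fitted on.
#' @param Y Outcome matrix the component was fitted on.
#' @param t_super The component's super score.
#' @return List with `blocks` and `Y` (deflated), `p_blocks` (per-block
#'   loadings) and `y_loading`.
#' @export
deflate <- function(blocks, Y, t_super) {
  tt <- sum(t_super^2)
  if (tt < .Machine$double.eps)
    stop("zero-norm super score; cannot deflate", call. = FALSE)
  p_blocks <- lapply(blocks, function(Xb) drop(crossprod(Xb, t_super)) / tt)
  blocks <- mapply(function(Xb, p) Xb - tcrossprod(t_super, p),
                   blocks, p_blocks, SIMPLIFY = FALSE)
  Y <- as.matrix(Y)
  y_loading <- drop(crossprod(Y, t_super)) / tt
  Y <- Y - tcrossprod(t_super, y_loading)
  list(blocks = blocks, Y = Y, p_blocks = p_blocks, y_loading = y_loading)
}

#' Fit an asmbPLS-DA model
#'
#' Preprocesses the blocks (weighted centering, scaling) and the dummy-coded
#' outcome (weighted centering only), then extracts `n_components` sparse
#' components sequentially, deflating between components. The per-component,
#' per-block sparsity quantiles are given as a matrix; use [tune_quantiles()]
#' to choose them by cross-validation.
#'
#' @param x A [multiblock()] object (original scale).
#' @param y Factor of group labels.
#' @param quantile_table Numeric matrix, `n_components` rows by `B` columns,
#'   of sparsity quantiles in `[0, 1)`; a vector of length `B` is recycled to
#'   all components.
#' @param n_components Number of components `J >= 1`. Defaults to
#'   `nrow(quantile_table)`.
#' @param ... Passed to [fit_component()] (`tol`, `max_iter`).
#' @return An object of class `"asmbplsda"` with the fitted components
#'   (weights, loadings), preprocessing state, training super scores,
#'   training labels and the super-score group geometry used by the distance
#'   decision rules.
#' @export
#' @examples
#' set.seed(1)
#' x <- multiblock(list(a = matrix(rnorm(200), 20), b = matrix(rnorm(100), 20)))
#' y <- factor(rep(0:1, each = 10))
#' fit <- asmbplsda(x, y, quantile_table = c(0.5, 0.5), n_components = 2)
#' fit
asmbplsda <- function(x, y, quantile_table, n_components = NULL, ...) {
  stopifnot(inherits(x, "multiblock"))
  B <- length(x$blocks)
  if (is.null(dim(quantile_table))) {
    if (length(quantile_table) != B)
      stop("'quantile_table' vector must have one entry per block",
           call. = FALSE)
    J <- if (is.null(n_components)) 1L else as.integer(n_components)
    quantile_table <- matrix(quantile_table, nrow = J, ncol = B, byrow = TRUE)
  }
  quantile_table <- as.matrix(quantile_table)
  if (is.null(n_components)) n_components <- nrow(quantile_table)
  J <- as.integer(n_components)
  if (J < 1L || nrow(quantile_table) < J || ncol(quantile_table) != B)
    stop("'quantile_table' must have at least 'n_components' rows and one ",
         "column per block", call. = FALSE)
  if (any(quantile_table < 0 | quantile_table >= 1))
    stop("quantiles must lie in [0, 1)", call. = FALSE)
  colnames(quantile_table) <- names(x$blocks)

  y <- droplevels(as.factor(y))
  pp <- weighted_center_scale(x, y)
  Xdef <- pp$x$blocks
  Ydef <- pp$y
  n <- n_samples(x)
  Tmat <- matrix(0, n, J, dimnames = list(x$sample_ids,
                                          paste0("comp", seq_len(J))))
  components <- vector("list", J)
  for (j in seq_len(J)) {
    cf <- tryCatch(
      fit_component(Xdef, Ydef, quantile_table[j, ], ...),
      error = function(e) stop("component ", j, ": ", conditionMessage(e),
                               call. = FALSE))
    d <- deflate(Xdef, Ydef, cf$t_super)
    Xdef <- d$blocks
    Ydef <- d$Y
    Tmat[, j] <- cf$t_super
    components[[j]] <- list(
      block_weights = cf$block_weights,
      super_weight = cf$super_weight,
      q = cf$q,
      p_blocks = d$p_blocks,
      y_loading = d$y_loading,
      lambdas = cf$lambdas,
      quantiles = quantile_table[j, ],
      support = cf$support,
      iterations = cf$iterations)
  }
  outcome_type <- if (length(levels(y)) == 2L) "binary" else "multiclass"
  model <- structure(list(
    components = components,
    preprocess = pp$state,
    outcome_type = outcome_type,
    levels = levels(y),
    labels = y,
    super_scores = Tmat,
    group_sizes = as.integer(table(y)),
    quantile_table = quantile_table[seq_len(J), , drop = FALSE],
    n_components = J,
    call = match.call()
  ), class = "asmbplsda")
  model$geometry <- group_geometry(Tmat, y)
  model
}

#' @export
print.asmbplsda <- function(x, ...) {
  cat("asmbPLS-DA model: ", x$n_components, " component(s), ",
      length(x$preprocess$block_sizes), " block(s), ",
      x$outcome_type, " outcome (", paste(x$levels, collapse = "/"),
      ")\n", sep = "")
  sel <- selected_features(x)
  cat("selected features per block:",
      paste(vapply(sel, length, integer(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Features selected by a fitted model
#'
#' The union of the non-zero-weight features across all fitted components,
#' per block.
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param n_components How many components to pool over (default all).
#' @return Named list (one element per block) of selected feature names.
#' @export
selected_features <- function(model, n_components = model$n_components) {
  stopifnot(inherits(model, "asmbplsda"))
  B <- length(model$preprocess$block_sizes)
  out <- vector("list", B)
  names(out) <- names(model$preprocess$block_sizes)
  for (b in seq_len(B)) {
    feats <- character(0)
    for (j in seq_len(n_components)) {
      w <- model$components[[j]]$block_weights[[b]]
      feats <- union(feats, names(w)[w != 0])
    }
    out[[b]] <- feats
  }
  out
}

#' Super scores for new samples
#'
#' Applies the stored preprocessing, then reproduces each component's block
#' scores and super score with the stored weights, deflating the new data
#' with the stored loadings between components. On the training data this
#' returns the stored training super scores.
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param newdata A [multiblock()] with the model's block structure.
#' @param n_components Number of components to compute (default all).
#' @return Matrix `n_new` by `n_components` of super scores.
#' @export
super_scores <- function(model, newdata, n_components = model$n_components) {
  stopifnot(inherits(model, "asmbplsda"))
  J <- as.integer(n_components)
  if (J < 1L || J > model$n_components)
    stop("'n_components' must be between 1 and ", model$n_components,
         call. = FALSE)
  Xc <- apply_center_scale(model$preprocess, newdata)$blocks
  m <- vapply(Xc, ncol, integer(1))
  n <- nrow(Xc[[1L]])
  Tmat <- matrix(0, n, J, dimnames = list(newdata$sample_ids,
                                          paste0("comp", seq_len(J))))
  for (j in seq_len(J)) {
    comp <- model$components[[j]]
    tb <- vapply(seq_along(Xc), function(b)
      drop(Xc[[b]] %*% comp$block_weights[[b]]) / sqrt(m[b]), numeric(n))
    if (n == 1L) tb <- matrix(tb, nrow = 1L)
    t_super <- drop(tb %*% comp$super_weight)
    Tmat[, j] <- t_super
    if (j < J)
      for (b in seq_along(Xc))
        Xc[[b]] <- Xc[[b]] - tcrossprod(t_super, comp$p_blocks[[b]])
  }
  Tmat
}

#' Y-estimates for new samples
#'
#' Accumulates the per-component rank-one predictions
#' `t_super %*% t(y_loading)` over the first `n_components` components.
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param newdata A [multiblock()], or `NULL` to use precomputed `scores`.
#' @param n_components Number of components used in the prediction.
#' @param scores Optional precomputed super-score matrix (at least
#'   `n_components` columns) to avoid recomputation.
#' @param shift If `TRUE` (default) the stored Y offsets are added back so
#'   the estimates live on the original 0/1 indicator scale; if `FALSE` the
#'   estimates are on the centered scale.
#' @return Matrix of Y-estimates (`n_new` rows; one column for binary, `G`
#'   for multiclass).
#' @export
predict_y <- function(model, newdata = NULL,
                      n_components = model$n_components,
                      scores = NULL, shift = TRUE) {
  stopifnot(inherits(model, "asmbplsda"))
  J <- as.integer(n_components)
  if (J == 0L) {
    n <- if (!is.null(scores)) nrow(scores) else n_samples(newdata)
    est <- matrix(0, n, length(model$preprocess$y_offsets))
    colnames(est) <- names(model$preprocess$y_offsets)
    if (shift) est <- sweep(est, 2L, model$preprocess$y_offsets, "+")
    return(est)
  }
  if (is.null(scores)) scores <- super_scores(model, newdata, J)
  yl <- do.call(rbind, lapply(model$components[seq_len(J)],
                              function(cm) cm$y_loading))
  est <- scores[, seq_len(J), drop = FALSE] %*% yl
  colnames(est) <- names(model$preprocess$y_offsets)
  if (shift) est <- sweep(est, 2L, model$preprocess$y_offsets, "+")
  est
}
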