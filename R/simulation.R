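#' Simulation scenario for the two-block benchmark generator
#'
#' Parameterizes the synthetic multi-omics generator: two correlated
#' multivariate-normal blocks with `q_h` (block 1) and `p_h` (block 2)
#' highly correlated features, planted relevant features (the first ten of
#' block 1 and the first five of block 2), four variable-order structures,
#' and binary or three-class outcomes simulated through (multinomial)
#' logistic models at noise scale `r`.
#'
#' @param n Number of training samples (and of test samples).
#' @param q,q_h Block-1 feature count and highly-correlated count
#'   (defaults 1000 and 100).
#' @param p,p_h Block-2 counts; the benchmark settings are `(50, 5)`,
#'   `(200, 20)` and `(1000, 100)`.
#' @param structure One of `"cor"` (all relevant features highly
#'   correlated), `"order"` (first six of block 1 and first three of block 2
#'   highly correlated), `"random"` (random column order) or `"inverse"`
#'   (no relevant feature highly correlated).
#' @param r Noise scale multiplying the extra normal noise in the linear
#'   predictor; the benchmark uses 0, 1, 2, 3 and 5.
#' @param outcome `"binary"` or `"multiclass"` (three groups).
#' @param seed Integer seed controlling the whole dataset draw.
#' @return A validated list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n = 100L, q = 1000L, q_h = 100L, p = 50L,
                                p_h = 5L,
                                structure = c("cor", "order", "random",
                                              "inverse"),
                                r = 0, outcome = c("binary", "multiclass"),
                                seed = 1L) {
  structure_ <- match.arg(structure)
  outcome <- match.arg(outcome)
  if (q_h > q || p_h > p) stop("q_h <= q and p_h <= p required",
                               call. = FALSE)
  if (r < 0) stop("'r' must be non-negative", call. = FALSE)
  structure(list(n = as.integer(n), q = as.integer(q), q_h = as.integer(q_h),
                 p = as.integer(p), p_h = as.integer(p_h),
                 structure = structure_, r = r, outcome = outcome,
                 seed = as.integer(seed),
                 n_relevant = c(10L, 5L), n_relevant_high_order = c(6L, 3L)),
            class = "simulation_scenario")
}

#' Build a positive-definite covariance matrix with random correlations
#'
#' Off-diagonal entries are `c_ij * sd_i * sd_j` with `c_ij` drawn uniformly
#' from `[c_low, c_high]`; the matrix is then repaired to positive
#' definiteness by flooring its eigenvalues at `1e-8` times the largest and
#' rescaling the diagonal back to the target variances.
#'
#' @param sds Positive per-feature standard deviations.
#' @param c_low,c_high Correlation range (e.g. 0.6–0.9 for the highly
#'   correlated part, -0.5–0.5 elsewhere).
#' @return A symmetric positive-definite matrix with diagonal `sds^2`.
#'   Uses the current RNG state.
#' @export
build_covariance <- function(sds, c_low, c_high) {
  if (any(sds <= 0)) stop("'sds' must be positive", call. = FALSE)
  m <- length(sds)
  if (m == 1L) return(matrix(sds^2, 1L, 1L))
  C <- matrix(0, m, m)
  up <- upper.tri(C)
  C[up] <- stats::runif(sum(up), c_low, c_high)
  C <- C + t(C)
  diag(C) <- 1
  Sigma <- C * tcrossprod(sds)
  e <- eigen(Sigma, symmetric = TRUE)
  floor_ <- 1e-8 * max(e$values)
  if (min(e$values) < floor_) {
    vals <- pmax(e$values, floor_)
    Sigma <- e$vectors %*% (vals * t(e$vectors))
    d <- sds / sqrt(diag(Sigma))
    Sigma <- Sigma * tcrossprod(d)
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  Sigma
}

#' Column-order map realizing a variable structure
#'
#' Returns a permutation `perm` for one block such that
#' `X_final = X_raw[, perm]`, where raw columns `1..m_h` are the highly
#' correlated ones and the relevant features sit at final positions
#' `1..n_relevant`. `"cor"` puts highly correlated columns at all relevant
#' positions, `"order"` at the first `n_high` of them, `"inverse"` at none,
#' and `"random"` permutes everything; the non-constrained positions are
#' filled randomly.
#'
#' @param structure One of `"cor"`, `"order"`, `"random"`, `"inverse"`.
#' @param m,m_h Total and highly-correlated feature counts of the block.
#' @param n_relevant Number of relevant (first) positions.
#' @param n_high For `"order"`: how many of the relevant positions are
#'   highly correlated.
#' @return Integer permutation of `1..m`. Uses the current RNG state.
#' @export
structure_map <- function(structure, m, m_h, n_relevant, n_high) {
  high <- seq_len(m_h)
  low <- setdiff(seq_len(m), high)
  pick <- function(pool, k) if (k == 0L) integer(0)
                            else pool[sample.int(length(pool), k)]
  if (structure == "random") return(sample.int(m))
  if (structure == "cor") {
    if (m_h < n_relevant)
      stop("structure 'cor' infeasible: only ", m_h, " highly correlated ",
           "columns for ", n_relevant, " relevant positions", call. = FALSE)
    head_ <- pick(high, n_relevant)
  } else if (structure == "order") {
    if (m_h < n_high || (m - m_h) < (n_relevant - n_high))
      stop("structure 'order' infeasible for this block", call. = FALSE)
    head_ <- c(pick(high, n_high), pick(low, n_relevant - n_high))
  } else if (structure == "inverse") {
    if ((m - m_h) < n_relevant)
      stop("structure 'inverse' infeasible: only ", m - m_h,
           " non-highly-correlated columns for ", n_relevant,
           " relevant positions", call. = FALSE)
    head_ <- pick(low, n_relevant)
  } else stop("unknown structure: ", structure, call. = FALSE)
  rest <- setdiff(seq_len(m), head_)
  c(head_, rest[sample.int(length(rest))])
}

# Draw the two raw blocks: the highly correlated features of both blocks
# jointly MVN(mu_h, Sigma_h), the rest jointly MVN(mu_l, Sigma_l). Block-1
# features have mean 0 / variance 1, block-2 mean 5 / variance 3.
draw_raw_blocks <- function(n, scn, chol_h, chol_l, mu_h, mu_l) {
  rmvn <- function(n, mu, R)
    sweep(matrix(stats::rnorm(n * ncol(R)), n) %*% R, 2L, mu, "+")
  Xh <- rmvn(n, mu_h, chol_h)
  Xl <- rmvn(n, mu_l, chol_l)
  X1 <- cbind(Xh[, seq_len(scn$q_h), drop = FALSE],
              Xl[, seq_len(scn$q - scn$q_h), drop = FALSE])
  X2 <- cbind(Xh[, scn$q_h + seq_len(scn$p_h), drop = FALSE],
              Xl[, (scn$q - scn$q_h) + seq_len(scn$p - scn$p_h),
                 drop = FALSE])
  list(X1 = X1, X2 = X2)
}

#' Simulate the two correlated predictor blocks
#'
#' Draws one realization of the raw blocks (before outcome simulation) for
#' a scenario, with the column order arranged by [structure_map()]. Mainly
#' useful for inspecting the generator; [generate_scenario()] produces the
#' full dataset.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with matrices `X1` (`n` by `q`) and `X2` (`n` by `p`) and
#'   the permutation `maps` used.
#' @export
simulate_blocks <- function(scenario) {
  scn <- scenario
  set.seed(scn$seed)
  maps <- list(
    structure_map(scn$structure, scn$q, scn$q_h, scn$n_relevant[1L],
                  scn$n_relevant_high_order[1L]),
    structure_map(scn$structure, scn$p, scn$p_h, scn$n_relevant[2L],
                  scn$n_relevant_high_order[2L]))
  sds_h <- c(rep(1, scn$q_h), rep(sqrt(3), scn$p_h))
  sds_l <- c(rep(1, scn$q - scn$q_h), rep(sqrt(3), scn$p - scn$p_h))
  mu_h <- c(rep(0, scn$q_h), rep(5, scn$p_h))
  mu_l <- c(rep(0, scn$q - scn$q_h), rep(5, scn$p - scn$p_h))
  Rh <- chol(build_covariance(sds_h, 0.6, 0.9))
  Rl <- chol(build_covariance(sds_l, -0.5, 0.5))
  raw <- draw_raw_blocks(scn$n, scn, Rh, Rl, mu_h, mu_l)
  list(X1 = raw$X1[, maps[[1L]], drop = FALSE],
       X2 = raw$X2[, maps[[2L]], drop = FALSE],
       maps = maps)
}

#' Simulate a binary outcome from the scaled blocks
#'
#' The blocks are centered and scaled, the linear predictor is
#' `eta = X1s b1 + X2s b2 + r * e` with the non-zero coefficients (first ten
#' of block 1, first five of block 2) drawn `N(0, 5)` and
#' `e ~ N(0, 5 I_n)`, and `Y_i ~ Bernoulli(1 / (1 + exp(-eta_i)))`.
#'
#' @param X1,X2 Raw block matrices (column order final).
#' @param r Noise scale.
#' @param beta Optional list `list(b1, b2)` of full-length coefficient
#'   vectors; drawn afresh if `NULL`. Supplying all-zero coefficients gives
#'   class probability 0.5 for every sample.
#' @return List with `y` (0/1 integer vector), `beta`, `eta` and `prob`.
#'   Uses the current RNG state.
#' @export
simulate_binary_outcome <- function(X1, X2, r, beta = NULL) {
  X1s <- scale(X1)
  X2s <- scale(X2)
  n <- nrow(X1)
  if (is.null(beta)) {
    b1 <- numeric(ncol(X1)); b1[1:10] <- stats::rnorm(10, sd = sqrt(5))
    b2 <- numeric(ncol(X2)); b2[1:5] <- stats::rnorm(5, sd = sqrt(5))
    beta <- list(b1 = b1, b2 = b2)
  }
  e <- stats::rnorm(n, sd = sqrt(5))
  eta <- drop(X1s %*% beta$b1 + X2s %*% beta$b2) + r * e
  prob <- stats::plogis(eta)
  y <- stats::rbinom(n, 1L, prob)
  list(y = y, beta = beta, eta = eta, prob = prob)
}

#' Simulate a three-class outcome from the scaled blocks
#'
#' Class 1 is the baseline with an all-zero linear predictor; classes 2 and
#' 3 each get independent coefficient sets with the same sparsity pattern as
#' the binary case plus `r * e_g` noise. Class probabilities are the
#' softmax of the three linear predictors (with max subtraction for
#' numerical stability) and each sample receives one multinomial draw.
#'
#' @inheritParams simulate_binary_outcome
#' @param beta Optional list `list(class2 = list(b1, b2),
#'   class3 = list(b1, b2))`.
#' @return List with `y` (integer class in 1..3), `Y` (n by 3 indicator
#'   matrix), `beta` and `prob`. Uses the current RNG state.
#' @export
simulate_multiclass_outcome <- function(X1, X2, r, beta = NULL) {
  X1s <- scale(X1)
  X2s <- scale(X2)
  n <- nrow(X1)
  draw_beta <- function() {
    b1 <- numeric(ncol(X1)); b1[1:10] <- stats::rnorm(10, sd = sqrt(5))
    b2 <- numeric(ncol(X2)); b2[1:5] <- stats::rnorm(5, sd = sqrt(5))
    list(b1 = b1, b2 = b2)
  }
  if (is.null(beta)) beta <- list(class2 = draw_beta(),
                                  class3 = draw_beta())
  lp <- cbind(
    0,
    drop(X1s %*% beta$class2$b1 + X2s %*% beta$class2$b2) +
      r * stats::rnorm(n, sd = sqrt(5)),
    drop(X1s %*% beta$class3$b1 + X2s %*% beta$class3$b2) +
      r * stats::rnorm(n, sd = sqrt(5)))
  lp <- lp - apply(lp, 1L, max)
  ex <- exp(lp)
  prob <- ex / rowSums(ex)
  y <- vapply(seq_len(n), function(i)
    sample.int(3L, 1L, prob = prob[i, ]), integer(1))
  Y <- matrix(0L, n, 3L)
  Y[cbind(seq_len(n), y)] <- 1L
  list(y = y, Y = Y, beta = beta, prob = prob)
}

#' Generate a full simulated dataset (train + test)
#'
#' Builds the covariance matrices and the column-order maps once, draws one
#' coefficient set, then draws an `n`-sample training set and an independent
#' `n`-sample test set from the identical parameters (same covariances and
#' coefficients, fresh data and noise). If an outcome draw leaves a class
#' empty it is retried with fresh noise (up to 20 times).
#'
#' @param scenario A [simulation_scenario()].
#' @return An object of class `"simulated_dataset"`: `x` and `y` (training
#'   [multiblock()] and factor labels), `x_test`, `y_test`, `truth` (list of
#'   relevant feature indices per block: `1:10` and `1:5`), `maps` (the
#'   column-order permutations), `beta` and `scenario`.
#' @export
generate_scenario <- function(scenario) {
  scn <- scenario
  stopifnot(inherits(scn, "simulation_scenario"))
  set.seed(scn$seed)
  maps <- list(
    structure_map(scn$structure, scn$q, scn$q_h, scn$n_relevant[1L],
                  scn$n_relevant_high_order[1L]),
    structure_map(scn$structure, scn$p, scn$p_h, scn$n_relevant[2L],
                  scn$n_relevant_high_order[2L]))
  sds_h <- c(rep(1, scn$q_h), rep(sqrt(3), scn$p_h))
  sds_l <- c(rep(1, scn$q - scn$q_h), rep(sqrt(3), scn$p - scn$p_h))
  mu_h <- c(rep(0, scn$q_h), rep(5, scn$p_h))
  mu_l <- c(rep(0, scn$q - scn$q_h), rep(5, scn$p - scn$p_h))
  Rh <- chol(build_covariance(sds_h, 0.6, 0.9))
  Rl <- chol(build_covariance(sds_l, -0.5, 0.5))

  beta <- NULL
  draw_set <- function(prefix) {
    raw <- draw_raw_blocks(scn$n, scn, Rh, Rl, mu_h, mu_l)
    X1 <- raw$X1[, maps[[1L]], drop = FALSE]
    X2 <- raw$X2[, maps[[2L]], drop = FALSE]
    colnames(X1) <- sprintf("b1_f%04d", seq_len(scn$q))
    colnames(X2) <- sprintf("b2_f%04d", seq_len(scn$p))
    for (attempt in seq_len(20L)) {
      if (scn$outcome == "binary") {
        out <- simulate_binary_outcome(X1, X2, scn$r, beta = beta)
        y <- factor(out$y, levels = c(0L, 1L))
      } else {
        out <- simulate_multiclass_outcome(X1, X2, scn$r, beta = beta)
        y <- factor(paste0("G", out$y), levels = c("G1", "G2", "G3"))
      }
      beta <<- out$beta
      if (all(table(y) > 0L)) break
      if (attempt == 20L)
        stop("could not draw a non-degenerate outcome in 20 attempts",
             call. = FALSE)
    }
    ids <- paste0(prefix, seq_len(scn$n))
    list(x = multiblock(list(block1 = X1, block2 = X2), sample_ids = ids),
         y = y)
  }
  train <- draw_set("tr")
  test <- draw_set("te")
  structure(list(
    x = train$x, y = train$y, x_test = test$x, y_test = test$y,
    truth = list(block1 = 1:10, block2 = 1:5),
    maps = maps, beta = beta, scenario = scn
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  scn <- x$scenario
  cat("simulated two-block dataset: n =", scn$n, "(+", scn$n, "test ),",
      "q =", scn$q, ", p =", scn$p, "\n")
  cat("structure =", scn$structure, ", r =", scn$r, ", outcome =",
      scn$outcome, ", seed =", scn$seed, "\n")
  invisible(x)
}
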