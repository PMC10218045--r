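# Small in-code fixtures shared across tests.

# n samples, per-block feature counts m (vector), standard normal entries.
random_multiblock <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  multiblock(lapply(seq_along(m), function(b) matrix(rnorm(n * m[b]), n)),
             block_names = paste0("block", seq_along(m)))
}

# Balanced binary labels 0/1 (level "1" is the group coded 1).
balanced_binary <- function(n) factor(rep(0:1, length.out = n),
                                      levels = 0:1)

# Two-block dataset where the outcome depends on the first features of
# block 1, so that fits have signal to find.
signal_dataset <- function(n = 60, m = c(20, 10), seed = 1,
                           n_signal = 4, strength = 2) {
  set.seed(seed)
  x <- random_multiblock(n, m)
  y <- balanced_binary(n)
  shift <- strength * (as.numeric(y) - 1.5)
  for (j in seq_len(n_signal))
    x$blocks[[1]][, j] <- x$blocks[[1]][, j] + shift
  list(x = x, y = y)
}

# Manually centered single-block inputs for direct fit_component calls.
centered_inputs <- function(X, y01) {
  Y <- matrix(y01 - mean(y01), ncol = 1)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  list(X = Xc, Y = Y)
}
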