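#' Weighted centering and scaling of a multi-block dataset
#'
#' Centers every predictor column by the average of its per-group means (the
#' "weighted center"), then scales it by its standard deviation; the
#' dummy-coded outcome is centered the same way but not scaled. With equal
#' group sizes the weighted center reduces to the ordinary column mean; with
#' unequal sizes it keeps the decision boundary from drifting toward the
#' larger group.
#'
#' @param x A [multiblock()] object.
#' @param y Factor of group labels (one per sample).
#' @return A list with elements `x` (centered/scaled `multiblock`), `y`
#'   (centered dummy outcome matrix) and `state`, a `"preprocess_state"`
#'   object holding the per-block offsets/scales and the Y offsets needed to
#'   preprocess new samples and to re-shift Y-estimates.
#' @seealso [apply_center_scale()]
#' @export
weighted_center_scale <- function(x, y) {
  stopifnot(inherits(x, "multiblock"))
  y <- droplevels(as.factor(y))
  if (length(y) != n_samples(x))
    stop("'y' must have one label per sample", call. = FALSE)
  Y <- dummy_code(y)
  lev <- attr(Y, "levels")

  x_offsets <- vector("list", length(x$blocks))
  x_scales <- vector("list", length(x$blocks))
  names(x_offsets) <- names(x_scales) <- names(x$blocks)
  blocks <- x$blocks
  for (b in seq_along(blocks)) {
    Xb <- blocks[[b]]
    off <- weighted_col_center(Xb, y)
    sds <- apply(Xb, 2L, stats::sd)
    zero <- which(sds < .Machine$double.eps^0.5)
    if (length(zero))
      stop("zero-variance feature(s) in block ", names(blocks)[b], ": ",
           paste(colnames(Xb)[utils::head(zero, 5L)], collapse = ", "),
           call. = FALSE)
    blocks[[b]] <- sweep(sweep(Xb, 2L, off, "-"), 2L, sds, "/")
    x_offsets[[b]] <- off
    x_scales[[b]] <- sds
  }
  y_offsets <- weighted_col_center(Y, y)
  Yc <- sweep(Y, 2L, y_offsets, "-")
  attr(Yc, "levels") <- lev

  state <- structure(
    list(x_offsets = x_offsets, x_scales = x_scales,
         y_offsets = y_offsets, levels = lev,
         block_sizes = block_sizes(x)),
    class = "preprocess_state")
  list(x = multiblock(blocks, sample_ids = x$sample_ids),
       y = Yc, state = state)
}

# Average of per-group column means: (Xbar_A + Xbar_B + ...)/G.
weighted_col_center <- function(M, y) {
  gm <- rowsum(M, y) / as.vector(table(y))
  colMeans(gm)
}

#' Apply stored preprocessing to new samples
#'
#' @param state A `"preprocess_state"` from [weighted_center_scale()].
#' @param x New [multiblock()] data with the same block structure as used at
#'   fitting time.
#' @return A `multiblock` with the stored offsets subtracted and scales
#'   divided out.
#' @export
apply_center_scale <- function(state, x) {
  stopifnot(inherits(state, "preprocess_state"), inherits(x, "multiblock"))
  sizes <- block_sizes(x)
  if (length(sizes) != length(state$block_sizes) ||
      any(sizes != state$block_sizes))
    stop("block structure of new data (",
         paste(sizes, collapse = ","), ") does not match the model (",
         paste(state$block_sizes, collapse = ","), ")", call. = FALSE)
  blocks <- x$blocks
  for (b in seq_along(blocks))
    blocks[[b]] <- sweep(sweep(blocks[[b]], 2L, state$x_offsets[[b]], "-"),
                         2L, state$x_scales[[b]], "/")
  multiblock(blocks, sample_ids = x$sample_ids)
}
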