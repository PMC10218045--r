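#' Multi-block predictor matrix
#'
#' Bundle several omics blocks (e.g. gene expression, miRNA, protein) measured
#' on the same samples into a single object. All blocks must share the sample
#' (row) order; feature names must be unique within each block.
#'
#' @param blocks List of numeric matrices (or data frames coercible to
#'   matrices), each `n` samples by `m_b` features, in the same row order.
#' @param sample_ids Optional character vector of length `n`. Defaults to the
#'   row names of the first block, or `"S1"..."Sn"`.
#' @param block_names Optional names for the blocks. Defaults to the list
#'   names, or `"block1"`, `"block2"`, ...
#'
#' @return An object of class `"multiblock"`: a list with elements `blocks`
#'   (the named list of matrices, row names set to `sample_ids`) and
#'   `sample_ids`.
#' @export
#' @examples
#' x <- multiblock(list(gene = matrix(rnorm(20), 5), mirna = matrix(rnorm(10), 5)))
#' x
multiblock <- function(blocks, sample_ids = NULL, block_names = NULL) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a non-empty list of matrices", call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    if (!is.numeric(b)) stop("all blocks must be numeric", call. = FALSE)
    b
  })
  if (is.null(block_names)) {
    block_names <- names(blocks)
    if (is.null(block_names) || any(block_names == ""))
      block_names <- paste0("block", seq_along(blocks))
  }
  names(blocks) <- block_names
  n <- nrow(blocks[[1L]])
  for (b in seq_along(blocks)) {
    if (nrow(blocks[[b]]) != n)
      stop("all blocks must have the same number of rows (block ", b,
           " has ", nrow(blocks[[b]]), ", expected ", n, ")", call. = FALSE)
    if (ncol(blocks[[b]]) < 1L)
      stop("block ", b, " has no features", call. = FALSE)
    if (is.null(colnames(blocks[[b]])))
      colnames(blocks[[b]]) <- paste0(names(blocks)[b], "_f",
                                      seq_len(ncol(blocks[[b]])))
    if (anyDuplicated(colnames(blocks[[b]])))
      stop("duplicate feature names in block ", b, call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(blocks[[1L]])
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("'sample_ids' must have length ", n, call. = FALSE)
  blocks <- lapply(blocks, function(b) { rownames(b) <- sample_ids; b })
  structure(list(blocks = blocks, sample_ids = sample_ids),
            class = "multiblock")
}

#' @export
print.multiblock <- function(x, ...) {
  dims <- vapply(x$blocks, ncol, integer(1))
  cat("multiblock: ", length(x$blocks), " block(s), ",
      length(x$sample_ids), " samples\n", sep = "")
  for (b in seq_along(dims))
    cat("  ", names(dims)[b], ": ", dims[b], " features\n", sep = "")
  invisible(x)
}

#' Number of samples / block sizes of a multiblock object
#' @param x A `multiblock` object.
#' @return `n_samples()` the number of samples; `block_sizes()` a named
#'   integer vector of per-block feature counts.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "multiblock"))
  length(x$sample_ids)
}

#' @rdname n_samples
#' @export
block_sizes <- function(x) {
  stopifnot(inherits(x, "multiblock"))
  vapply(x$blocks, ncol, integer(1))
}

# Row subset (used for CV folds); keeps block structure intact.
mb_rows <- function(x, idx) {
  multiblock(lapply(x$blocks, function(b) b[idx, , drop = FALSE]),
             sample_ids = x$sample_ids[idx], block_names = names(x$blocks))
}

#' Dummy-code a group outcome
#'
#' Groups are coded as 0/1 indicators: a single column (indicator of the
#' second level) when there are two groups, and one column per group when
#' there are three or more.
#'
#' @param labels Factor (or coercible) of group labels, one per sample.
#' @return A numeric indicator matrix with attributes `levels` (group levels)
#'   and `group_sizes` (named counts). One column for two groups, `G` columns
#'   for `G >= 3`.
#' @export
#' @examples
#' dummy_code(factor(c("ctrl", "case", "ctrl", "case")))
dummy_code <- function(labels) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  lev <- levels(labels)
  G <- length(lev)
  if (G < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes == 0L))
    stop("empty group: ", paste(lev[sizes == 0L], collapse = ", "),
         call. = FALSE)
  if (G == 2L) {
    Y <- matrix(as.numeric(labels == lev[2L]), ncol = 1L,
                dimnames = list(NULL, lev[2L]))
  } else {
    Y <- vapply(lev, function(l) as.numeric(labels == l),
                numeric(length(labels)))
    dimnames(Y) <- list(NULL, lev)
  }
  attr(Y, "levels") <- lev
  attr(Y, "group_sizes") <- as.integer(sizes)
  names(attr(Y, "group_sizes")) <- lev
  Y
}
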