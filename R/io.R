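#' Read multi-block data from delimited files
#'
#' Each block file is a delimited matrix with a header row of feature names
#' and the sample identifiers in the first column. Alternatively a single
#' matrix file plus a block map (two columns: feature, block) may be given.
#' Rows of all blocks and of the outcome file are aligned by sample id;
#' missing cells, non-numeric values and duplicate feature names are
#' rejected with their location.
#'
#' @param block_files Character vector of block file paths (or a single
#'   path when `block_map` is used).
#' @param outcome_file Two-column delimited file: sample id, group label.
#' @param block_map Optional path to a feature-to-block map used to split a
#'   single matrix into blocks.
#' @param sep Field separator (default `","`).
#' @return List with `x` (a [multiblock()]) and `y` (factor of group
#'   labels, in the same sample order).
#' @export
read_blocks <- function(block_files, outcome_file, block_map = NULL,
                        sep = ",") {
  read_one <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("file ", path, " needs an id column plus at least one feature",
           call. = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate sample ids in ", path, call. = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(M)))
      stop("duplicate feature names in ", path, ": ",
           paste(unique(colnames(M)[duplicated(colnames(M))]),
                 collapse = ", "), call. = FALSE)
    if (!is.numeric(M)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric values in ", path, ", column '",
           colnames(M)[bad], "'", call. = FALSE)
    }
    if (anyNA(M)) {
      idx <- which(is.na(M), arr.ind = TRUE)[1L, ]
      stop("missing value in ", path, " at sample '", ids[idx[1L]],
           "', feature '", colnames(M)[idx[2L]], "'", call. = FALSE)
    }
    rownames(M) <- ids
    M
  }
  mats <- lapply(block_files, read_one)
  if (!is.null(block_map)) {
    if (length(mats) != 1L)
      stop("'block_map' requires a single matrix file", call. = FALSE)
    map <- utils::read.table(block_map, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    M <- mats[[1L]]
    missing_feat <- setdiff(colnames(M), map[[1L]])
    if (length(missing_feat))
      stop("features absent from the block map: ",
           paste(utils::head(missing_feat, 5L), collapse = ", "),
           call. = FALSE)
    grp <- map[[2L]][match(colnames(M), map[[1L]])]
    mats <- lapply(split(seq_len(ncol(M)), grp),
                   function(j) M[, j, drop = FALSE])
  }
  ids <- rownames(mats[[1L]])
  for (b in seq_along(mats)) {
    if (!setequal(rownames(mats[[b]]), ids))
      stop("sample ids of block ", b, " do not match block 1",
           call. = FALSE)
    mats[[b]] <- mats[[b]][ids, , drop = FALSE]
  }
  out <- utils::read.table(outcome_file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  oid <- as.character(out[[1L]])
  if (!setequal(oid, ids))
    stop("sample ids of the outcome file do not match the blocks",
         call. = FALSE)
  y <- factor(out[[2L]][match(ids, oid)])
  list(x = multiblock(mats, sample_ids = ids), y = y)
}

# ---- model serialization ------------------------------------------------

mat_to_list <- function(M)
  list(dim = dim(M), dimnames = dimnames(M), data = as.vector(M))

list_to_mat <- function(l) {
  M <- matrix(unlist(l$data), l$dim[[1L]], l$dim[[2L]])
  if (!is.null(l$dimnames))
    dimnames(M) <- lapply(l$dimnames, function(d)
      if (is.null(d) || length(d) == 0L) NULL else unlist(d))
  M
}

#' Write a fitted model to JSON
#'
#' Serializes the model (components, preprocessing state, training super
#' scores and labels, configuration) as JSON at full floating-point
#' precision, so that a read-back model reproduces super scores exactly.
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "asmbplsda"))
  comps <- lapply(model$components, function(cm) list(
    block_weights = cm$block_weights,
    super_weight = cm$super_weight,
    q = cm$q,
    p_blocks = cm$p_blocks,
    y_loading = cm$y_loading,
    lambdas = cm$lambdas,
    quantiles = cm$quantiles,
    iterations = cm$iterations))
  obj <- list(
    format = "asmbplsda-model",
    version = 1L,
    outcome_type = model$outcome_type,
    levels = model$levels,
    labels = as.character(model$labels),
    n_components = model$n_components,
    quantile_table = mat_to_list(model$quantile_table),
    super_scores = mat_to_list(model$super_scores),
    preprocess = list(
      x_offsets = model$preprocess$x_offsets,
      x_scales = model$preprocess$x_scales,
      y_offsets = model$preprocess$y_offsets,
      block_sizes = model$preprocess$block_sizes),
    components = comps)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to the JSON model file.
#' @return The reconstructed `"asmbplsda"` model (group geometry is
#'   recomputed from the stored training super scores and labels).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "asmbplsda-model")
    stop("not an asmbplsda model file: ", path, call. = FALSE)
  obj$levels <- unlist(obj$levels)
  obj$labels <- unlist(obj$labels)
  obj$n_components <- unlist(obj$n_components)
  labels <- factor(obj$labels, levels = obj$levels)
  state <- structure(list(
    x_offsets = lapply(obj$preprocess$x_offsets, unlist),
    x_scales = lapply(obj$preprocess$x_scales, unlist),
    y_offsets = unlist(obj$preprocess$y_offsets),
    levels = obj$levels,
    block_sizes = unlist(obj$preprocess$block_sizes)),
    class = "preprocess_state")
  comps <- lapply(obj$components, function(cm) {
    w <- lapply(cm$block_weights, unlist)
    list(block_weights = w,
         super_weight = unlist(cm$super_weight),
         q = unlist(cm$q),
         p_blocks = lapply(cm$p_blocks, unlist),
         y_loading = unlist(cm$y_loading),
         lambdas = unlist(cm$lambdas),
         quantiles = unlist(cm$quantiles),
         support = lapply(w, function(v) which(v != 0)),
         iterations = cm$iterations)
  })
  Tmat <- list_to_mat(obj$super_scores)
  model <- structure(list(
    components = comps,
    preprocess = state,
    outcome_type = obj$outcome_type,
    levels = obj$levels,
    labels = labels,
    super_scores = Tmat,
    group_sizes = as.integer(table(labels)),
    quantile_table = list_to_mat(obj$quantile_table),
    n_components = obj$n_components,
    call = NULL), class = "asmbplsda")
  model$geometry <- group_geometry(Tmat, labels)
  model
}

# ---- two-stage export / adapters ---------------------------------------

#' Export predictors for a downstream classifier
#'
#' After fitting, either the super scores of the first components or the
#' original-scale submatrix of the selected features can serve as predictors
#' for an external classifier (e.g. LDA or random forest).
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param x A [multiblock()] (training or new samples).
#' @param mode `"super_scores"` or `"selected_features"`.
#' @param n_components Components used (default all fitted).
#' @return A numeric matrix; for `"selected_features"` the columns carry a
#'   `"blocks"` attribute with each feature's block of origin.
#' @export
export_two_stage <- function(model, x,
                             mode = c("super_scores", "selected_features"),
                             n_components = model$n_components) {
  mode <- match.arg(mode)
  if (mode == "super_scores")
    return(super_scores(model, x, n_components))
  sel <- selected_features(model, n_components)
  if (sum(lengths(sel)) == 0L)
    stop("the model selected no features", call. = FALSE)
  parts <- lapply(seq_along(sel), function(b)
    x$blocks[[b]][, sel[[b]], drop = FALSE])
  out <- do.call(cbind, parts)
  rownames(out) <- x$sample_ids
  attr(out, "blocks") <- rep(names(x$blocks), lengths(sel))
  out
}

#' Two-stage classification through LDA or random forest
#'
#' Thin adapter implementing the two-stage strategy: the fitted model's
#' super scores or selected features become predictors for linear
#' discriminant analysis ([MASS::lda()]) or a random forest
#' ([randomForest::randomForest()]), which does the final classification.
#'
#' @param model A fitted `"asmbplsda"` model.
#' @param x Training [multiblock()] and
#' @param y its labels.
#' @param newdata [multiblock()] of samples to classify.
#' @param method `"lda"` or `"rf"`.
#' @param mode Passed to [export_two_stage()].
#' @param ... Passed to the downstream classifier.
#' @return Factor of predicted labels for `newdata`.
#' @export
two_stage_classify <- function(model, x, y, newdata,
                               method = c("lda", "rf"),
                               mode = c("selected_features",
                                        "super_scores"), ...) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  tr <- export_two_stage(model, x, mode)
  te <- export_two_stage(model, newdata, mode)
  y <- droplevels(as.factor(y))
  if (method == "lda") {
    fit <- MASS::lda(tr, grouping = y, ...)
    stats::predict(fit, te)$class
  } else {
    fit <- randomForest::randomForest(tr, y, ...)
    stats::predict(fit, te)
  }
}
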