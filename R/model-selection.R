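#' Repeated stratified K-fold assignments
#'
#' Splits the samples into `K` roughly equal folds with the class ratios
#' preserved in every fold (per-class fold sizes differ by at most one), and
#' repeats the randomized split `N_CV` times.
#'
#' @param labels Factor of class labels; every class must have at least `K`
#'   samples.
#' @param K Number of folds.
#' @param N_CV Number of independent repetitions.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer matrix, `n` rows by `N_CV` columns, of fold ids in
#'   `1..K`.
#' @export
stratified_repeated_folds <- function(labels, K = 5L, N_CV = 10L,
                                      seed = NULL) {
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  K <- as.integer(K)
  N_CV <- as.integer(N_CV)
  sizes <- table(labels)
  small <- names(sizes)[sizes < K]
  if (length(small))
    stop("class(es) smaller than K = ", K, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  folds <- matrix(0L, n, N_CV)
  for (r in seq_len(N_CV)) {
    for (lev in levels(labels)) {
      idx <- which(labels == lev)
      # permuted fold ids; which folds carry the remainder is randomized too
      ids <- sample.int(K)[(seq_along(idx) - 1L) %% K + 1L]
      folds[idx, r] <- ids[sample.int(length(idx))]
    }
  }
  folds
}

#' Average cross-validated balanced accuracy
#'
#' The mean over folds and repetitions of the per-fold balanced accuracies
#' (a flat average, since all repetitions use the same number of folds).
#'
#' @param fold_bas Numeric vector or `K` by `N_CV` matrix of per-fold
#'   balanced accuracies; no missing values allowed.
#' @return The average balanced accuracy.
#' @export
cv_balanced_accuracy <- function(fold_bas) {
  if (anyNA(fold_bas))
    stop("missing fold balanced accuracy", call. = FALSE)
  mean(fold_bas)
}

#' Choose the number of components from per-component CV accuracies
#'
#' Starts at one component and moves to the next as long as adding it
#' improves the cross-validated balanced accuracy by at least 0.005, i.e.
#' while `BA[comp] + 0.005 <= BA[comp + 1]`.
#'
#' @param bas Numeric vector of per-component balanced accuracies.
#' @return The selected number of components.
#' @export
#' @examples
#' select_n_components(c(0.70, 0.71, 0.712)) # 2
select_n_components <- function(bas) {
  comp <- 1L
  while (comp < length(bas) && bas[comp] + 0.005 <= bas[comp + 1L])
    comp <- comp + 1L
  comp
}

# Validation-fold labels for a candidate component, from cached fold state.
cv_predict_fold <- function(st, cf, y_loading, rule, lev, outcome_type) {
  m <- vapply(st$Xva, ncol, integer(1))
  nva <- nrow(st$Xva[[1L]])
  tb <- vapply(seq_along(st$Xva), function(b)
    drop(st$Xva[[b]] %*% cf$block_weights[[b]]) / sqrt(m[b]), numeric(nva))
  if (nva == 1L) tb <- matrix(tb, nrow = 1L)
  t_super_va <- drop(tb %*% cf$super_weight)
  yest_va <- st$yest_va + tcrossprod(t_super_va, y_loading)
  shifted <- sweep(yest_va, 2L, st$y_offsets, "+")
  pred <- switch(rule,
    fixed_cutoff = classify_fixed_cutoff(shifted, lev),
    max_y = classify_max_y(shifted, lev),
    ed_super = ,
    md_super = {
      T_tr <- cbind(st$T_tr, cf$t_super)
      T_va <- cbind(st$T_va, t_super_va)
      geom <- group_geometry(T_tr, st$y_tr)
      if (rule == "ed_super") classify_euclidean(T_va, geom)
      else classify_mahalanobis(T_va, geom)
    },
    stop("unsupported tuning rule: ", rule, call. = FALSE))
  list(pred = pred, t_super_va = t_super_va, yest_va = yest_va)
}

#' Tune the sparsity quantiles by repeated stratified cross-validation
#'
#' Chooses, sequentially for each component, the per-block quantile
#' combination with the highest average cross-validated balanced accuracy
#' ([cv_balanced_accuracy()]), holding the combinations already chosen for
#' earlier components fixed. The candidate set for a component is the
#' cartesian product of the per-block quantile lists (the same lists are
#' reused for every component); ties go to the first candidate in grid
#' order. A candidate whose component fit fails in a fold scores 0 for that
#' fold, and the failure is logged in the result.
#'
#' @param x A [multiblock()] object.
#' @param y Factor of group labels.
#' @param quantiles Named list, one numeric vector of candidate quantiles in
#'   `[0, 1)` per block.
#' @param n_components Number of components to tune (default 3).
#' @param K,N_CV Folds and repetitions (defaults 5 and 10).
#' @param rule Decision rule used to score validation folds. Defaults to
#'   `"fixed_cutoff"` (binary) or `"max_y"` (multiclass); `"ed_super"` and
#'   `"md_super"` are also supported.
#' @param seed Optional integer seed.
#' @return An object of class `"asmbplsda_cv"`: `quantile_table` (chosen
#'   `J` by `B` matrix), `ba` (per-component best balanced accuracy),
#'   `n_selected` (from [select_n_components()]), `cv_table` (all evaluated
#'   combinations and their accuracies), `failures`, plus the settings.
#' @export
tune_quantiles <- function(x, y, quantiles, n_components = 3L, K = 5L,
                           N_CV = 10L, rule = NULL, seed = NULL) {
  stopifnot(inherits(x, "multiblock"))
  B <- length(x$blocks)
  if (!is.list(quantiles) || length(quantiles) != B)
    stop("'quantiles' must be a list with one candidate vector per block",
         call. = FALSE)
  if (any(unlist(quantiles) < 0 | unlist(quantiles) >= 1))
    stop("candidate quantiles must lie in [0, 1)", call. = FALSE)
  names(quantiles) <- names(x$blocks)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  outcome_type <- if (length(lev) == 2L) "binary" else "multiclass"
  if (is.null(rule))
    rule <- if (outcome_type == "binary") "fixed_cutoff" else "max_y"
  J <- as.integer(n_components)

  cand <- as.matrix(expand.grid(quantiles, KEEP.OUT.ATTRS = FALSE))
  nc_cand <- nrow(cand)
  folds <- stratified_repeated_folds(y, K, N_CV, seed)
  n_folds <- K * N_CV

  # one cached state per (repetition, fold): preprocessed training data,
  # preprocessed validation data, and per-component running deflations
  states <- vector("list", n_folds)
  i <- 0L
  for (r in seq_len(N_CV)) for (k in seq_len(K)) {
    i <- i + 1L
    tr <- which(folds[, r] != k)
    va <- which(folds[, r] == k)
    pp <- weighted_center_scale(mb_rows(x, tr), y[tr])
    states[[i]] <- list(
      Xtr = pp$x$blocks, Ytr = pp$y,
      Xva = apply_center_scale(pp$state, mb_rows(x, va))$blocks,
      y_tr = y[tr], y_va = y[va],
      y_offsets = pp$state$y_offsets,
      T_tr = matrix(0, length(tr), 0L), T_va = matrix(0, length(va), 0L),
      yest_va = matrix(0, length(va), ncol(pp$y)))
  }

  chosen <- matrix(0, J, B, dimnames = list(paste0("comp", seq_len(J)),
                                            names(x$blocks)))
  ba_best <- numeric(J)
  cv_rows <- vector("list", J)
  failures <- list()

  for (l in seq_len(J)) {
    ba_cand <- numeric(nc_cand)
    for (ci in seq_len(nc_cand)) {
      fold_ba <- numeric(n_folds)
      for (fi in seq_len(n_folds)) {
        st <- states[[fi]]
        res <- tryCatch({
          cf <- fit_component(st$Xtr, st$Ytr, cand[ci, ])
          dl <- deflate(st$Xtr, st$Ytr, cf$t_super)
          pr <- cv_predict_fold(st, cf, dl$y_loading, rule, lev,
                                outcome_type)
          balanced_accuracy(st$y_va, pr$pred)
        }, error = function(e) {
          failures[[length(failures) + 1L]] <<- data.frame(
            component = l, candidate = ci, fold = fi,
            message = conditionMessage(e))
          0
        })
        fold_ba[fi] <- res
      }
      ba_cand[ci] <- cv_balanced_accuracy(fold_ba)
    }
    best <- which.max(ba_cand)  # first maximum in grid order
    chosen[l, ] <- cand[best, ]
    ba_best[l] <- ba_cand[best]
    cv_rows[[l]] <- data.frame(component = l, cand, ba = ba_cand,
                               check.names = FALSE)
    # fix the chosen combination: advance every fold state one component
    for (fi in seq_len(n_folds)) {
      st <- states[[fi]]
      cf <- fit_component(st$Xtr, st$Ytr, chosen[l, ])
      dl <- deflate(st$Xtr, st$Ytr, cf$t_super)
      pr <- cv_predict_fold(st, cf, dl$y_loading, rule, lev, outcome_type)
      st$Xtr <- dl$blocks
      st$Ytr <- dl$Y
      st$T_tr <- cbind(st$T_tr, cf$t_super)
      st$T_va <- cbind(st$T_va, pr$t_super_va)
      st$yest_va <- pr$yest_va
      for (b in seq_along(st$Xva))
        st$Xva[[b]] <- st$Xva[[b]] -
          tcrossprod(pr$t_super_va, dl$p_blocks[[b]])
      states[[fi]] <- st
    }
  }

  structure(list(
    quantile_table = chosen,
    ba = ba_best,
    n_selected = select_n_components(ba_best),
    cv_table = do.call(rbind, cv_rows),
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    K = K, N_CV = N_CV, rule = rule, seed = seed
  ), class = "asmbplsda_cv")
}

#' @export
print.asmbplsda_cv <- function(x, ...) {
  cat("asmbPLS-DA cross-validation (K = ", x$K, ", N_CV = ", x$N_CV,
      ", rule = ", x$rule, ")\n", sep = "")
  tab <- cbind(x$quantile_table, BA = round(x$ba, 4))
  print(tab)
  cat("selected components:", x$n_selected, "\n")
  invisible(x)
}

#' Plot the cross-validation accuracy surface
#'
#' Simple base-graphics view of the per-candidate balanced accuracies for
#' each component.
#'
#' @param x An `"asmbplsda_cv"` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.asmbplsda_cv <- function(x, ...) {
  tab <- x$cv_table
  comps <- sort(unique(tab$component))
  ba <- vapply(comps, function(l) tab$ba[tab$component == l],
               numeric(sum(tab$component == comps[1L])))
  graphics::matplot(ba, type = "b", pch = 19, lty = 1,
                    xlab = "quantile combination (grid order)",
                    ylab = "cross-validated balanced accuracy", ...)
  graphics::legend("bottomright", legend = paste("component", comps),
                   col = seq_along(comps), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Cross-validated performance of the decision rules
#'
#' With the quantile combinations fixed (typically the optimum from
#' [tune_quantiles()]), runs repeated stratified K-fold CV, applies every
#' requested decision rule to each validation fold, and averages the
#' confusion-derived metrics over folds. The result feeds the weighted and
#' ranked votes.
#'
#' @inheritParams tune_quantiles
#' @param quantile_table Fixed quantile matrix (`n_components` by `B`).
#' @param n_components Number of components fitted in each fold.
#' @param rules Character vector of base rules; defaults to all rules
#'   applicable to the outcome type.
#' @return Data frame with one row per rule: `rule`, `ba`, `accuracy`,
#'   `recall`, `precision`, `f1` (macro averages) and the derived vote
#'   `weight`.
#' @export
rule_performance_cv <- function(x, y, quantile_table, n_components = NULL,
                                rules = NULL, K = 5L, N_CV = 10L,
                                seed = NULL) {
  y <- droplevels(as.factor(y))
  outcome_type <- if (length(levels(y)) == 2L) "binary" else "multiclass"
  if (is.null(rules)) rules <- applicable_rules(outcome_type)
  folds <- stratified_repeated_folds(y, K, N_CV, seed)
  acc <- matrix(0, length(rules), 5L,
                dimnames = list(rules,
                                c("ba", "accuracy", "recall", "precision",
                                  "f1")))
  n_folds <- 0L
  for (r in seq_len(ncol(folds))) for (k in seq_len(max(folds[, r]))) {
    tr <- which(folds[, r] != k)
    va <- which(folds[, r] == k)
    fit <- asmbplsda(mb_rows(x, tr), y[tr], quantile_table,
                     n_components = n_components)
    for (rl in rules) {
      pred <- predict(fit, mb_rows(x, va), rule = rl)
      rep <- classification_report(y[va], pred)
      acc[rl, ] <- acc[rl, ] + c(rep$balanced_accuracy, rep$accuracy,
                                 rep$macro_recall, rep$macro_precision,
                                 rep$macro_f1)
    }
    n_folds <- n_folds + 1L
  }
  acc <- acc / n_folds
  out <- data.frame(rule = rules, acc, row.names = NULL)
  out$weight <- vote_weight(out$ba)
  out
}
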