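# Labels from one base decision rule, given precomputed scores/estimates.
base_rule_labels <- function(model, rule, n_components, scores_new,
                             yest_new, yest_train) {
  lev <- model$levels
  nc <- n_components
  switch(rule,
    fixed_cutoff = {
      if (model$outcome_type != "binary")
        stop("fixed cutoff applies to binary outcomes only", call. = FALSE)
      classify_fixed_cutoff(yest_new, lev)
    },
    max_y = {
      if (model$outcome_type != "multiclass")
        stop("Max Y applies to multiclass outcomes only", call. = FALSE)
      classify_max_y(yest_new, lev)
    },
    ed_super = {
      geom <- group_geometry(model$super_scores[, seq_len(nc), drop = FALSE],
                             model$labels)
      classify_euclidean(scores_new[, seq_len(nc), drop = FALSE], geom)
    },
    md_super = {
      geom <- group_geometry(model$super_scores[, seq_len(nc), drop = FALSE],
                             model$labels)
      classify_mahalanobis(scores_new[, seq_len(nc), drop = FALSE], geom)
    },
    ed_y = {
      if (model$outcome_type != "multiclass")
        stop("the Euclidean rule on Y-estimates applies to multiclass ",
             "outcomes only", call. = FALSE)
      geom <- group_geometry(yest_train, model$labels)
      classify_euclidean(yest_new, geom)
    },
    pca_md = {
      classify_pca_md(yest_new, yest_train, model$labels)
    },
    stop("unknown decision rule: ", rule, call. = FALSE)
  )
}

#' Predict group membership for new samples
#'
#' Computes super scores and Y-estimates for `newdata` and translates them
#' into group labels with the requested decision rule or vote scheme.
#'
#' @param object A fitted `"asmbplsda"` model.
#' @param newdata A [multiblock()] with the model's block structure.
#' @param n_components Number of components used (default: all fitted).
#' @param rule One of `"fixed_cutoff"`, `"max_y"`, `"ed_super"`, `"ed_y"`,
#'   `"md_super"`, `"pca_md"`, `"vote_unweighted"`, `"vote_weighted"`,
#'   `"vote_ranked"`. The default is `"fixed_cutoff"` for binary and
#'   `"max_y"` for multiclass outcomes. Vote schemes combine all base rules
#'   applicable to the outcome type.
#' @param performances Cross-validated per-rule metrics from
#'   [rule_performance_cv()]; required by the weighted and ranked votes.
#' @param type `"class"` (default) for labels, `"response"` for Y-estimates
#'   on the indicator scale, `"scores"` for super scores.
#' @param ... Unused.
#' @return A factor of predicted labels, or a numeric matrix for
#'   `type = "response"` / `"scores"`.
#' @export
predict.asmbplsda <- function(object, newdata,
                              n_components = object$n_components,
                              rule = NULL, performances = NULL,
                              type = c("class", "response", "scores"), ...) {
  type <- match.arg(type)
  nc <- as.integer(n_components)
  scores_new <- super_scores(object, newdata, nc)
  if (type == "scores") return(scores_new)
  yest_new <- predict_y(object, scores = scores_new, n_components = nc)
  if (type == "response") return(yest_new)
  if (is.null(rule))
    rule <- if (object$outcome_type == "binary") "fixed_cutoff" else "max_y"
  yest_train <- predict_y(object, scores = object$super_scores,
                          n_components = nc)
  if (rule %in% c("vote_unweighted", "vote_weighted", "vote_ranked")) {
    base <- applicable_rules(object$outcome_type)
    labs <- lapply(base, function(r)
      base_rule_labels(object, r, nc, scores_new, yest_new, yest_train))
    names(labs) <- base
    if (rule == "vote_unweighted") return(vote_unweighted(labs))
    if (is.null(performances))
      stop("'", rule, "' needs cross-validated rule performances; supply ",
           "the result of rule_performance_cv()", call. = FALSE)
    perf <- performances[match(base, performances$rule), , drop = FALSE]
    if (anyNA(perf$ba))
      stop("performances are missing for rule(s): ",
           paste(base[is.na(perf$ba)], collapse = ", "), call. = FALSE)
    if (rule == "vote_weighted") return(vote_weighted(labs, perf))
    sel <- vote_ranked(perf)
    return(labs[[sel]])
  }
  base_rule_labels(object, rule, nc, scores_new, yest_new, yest_train)
}
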