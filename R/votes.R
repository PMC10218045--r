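#' Vote weight from balanced accuracy
#'
#' `log(BA / (1 - BA))`, the logit of the rule's cross-validated balanced
#' accuracy; rules no better than chance (`BA <= 0.5`) get weight 0. BA is
#' clamped at `1 - 1e-6` so a perfect rule gets a large finite weight.
#'
#' @param ba Numeric vector of balanced accuracies in `[0, 1]`.
#' @return Numeric vector of non-negative weights.
#' @export
#' @examples
#' vote_weight(c(0.5, 0.75, 1))
vote_weight <- function(ba) {
  if (any(is.na(ba)) || any(ba < 0 | ba > 1))
    stop("balanced accuracies must lie in [0, 1]", call. = FALSE)
  ba <- pmin(ba, 1 - 1e-6)
  ifelse(ba <= 0.5, 0, log(ba / (1 - ba)))
}

# Shared engine: per-sample weighted plurality; ties among top-scoring
# labels go to the vote of the earliest rule among the tied labels.
vote_engine <- function(rule_labels, weights) {
  if (length(rule_labels) < 2L)
    stop("need at least two rules to vote", call. = FALSE)
  n <- length(rule_labels[[1L]])
  if (any(vapply(rule_labels, length, integer(1)) != n))
    stop("rule label vectors have inconsistent lengths", call. = FALSE)
  lev <- levels(as.factor(rule_labels[[1L]]))
  for (r in seq_along(rule_labels))
    lev <- union(lev, levels(as.factor(rule_labels[[r]])))
  votes <- vapply(rule_labels, function(l) as.character(l),
                  character(n))
  if (n == 1L) votes <- matrix(votes, nrow = 1L)
  out <- character(n)
  for (i in seq_len(n)) {
    score <- numeric(length(lev))
    names(score) <- lev
    for (r in seq_along(rule_labels))
      score[votes[i, r]] <- score[votes[i, r]] + weights[r]
    best <- max(score)
    cand <- names(score)[score >= best - 1e-12]
    if (length(cand) == 1L) {
      out[i] <- cand
    } else {
      # earliest rule whose vote is among the tied candidates
      pick <- votes[i, match(TRUE, votes[i, ] %in% cand)]
      out[i] <- pick
    }
  }
  factor(out, levels = lev)
}

#' Unweighted vote
#'
#' Per-sample plurality over the labels of several decision rules, each rule
#' counting equally; ties are broken by the order in which the rules are
#' given.
#'
#' @param rule_labels List of per-rule predicted label vectors (factors of
#'   equal length).
#' @return Factor of combined labels.
#' @export
vote_unweighted <- function(rule_labels) {
  vote_engine(rule_labels, rep(1, length(rule_labels)))
}

#' Weighted vote
#'
#' Like [vote_unweighted()], but each rule's vote counts with the weight
#' [vote_weight()] derived from its cross-validated balanced accuracy.
#'
#' @param rule_labels List of per-rule predicted label vectors.
#' @param performances Either a numeric vector of balanced accuracies (one
#'   per rule) or a data frame with a `ba` column as returned by
#'   [rule_performance_cv()].
#' @return Factor of combined labels.
#' @export
vote_weighted <- function(rule_labels, performances) {
  ba <- if (is.data.frame(performances)) performances$ba else performances
  if (length(ba) != length(rule_labels))
    stop("need one performance per rule", call. = FALSE)
  vote_engine(rule_labels, vote_weight(ba))
}

#' Ranked vote
#'
#' Ranks the rules on each of five cross-validated metrics (balanced
#' accuracy, overall accuracy, recall, precision, F1; higher is better, ties
#' get average ranks), sums the ranks, and selects the rule with the highest
#' combined rank; ties go to the first rule.
#'
#' @param performances Data frame with one row per rule and columns `ba`,
#'   `accuracy`, `recall`, `precision`, `f1`.
#' @return The index of the selected rule, with attribute `combined_rank`
#'   (the per-rule rank sums).
#' @export
vote_ranked <- function(performances) {
  metrics <- c("ba", "accuracy", "recall", "precision", "f1")
  missing <- setdiff(metrics, names(performances))
  if (length(missing))
    stop("performances are missing metric(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ranks <- vapply(metrics, function(m)
    rank(performances[[m]], ties.method = "average"),
    numeric(nrow(performances)))
  if (nrow(performances) == 1L) ranks <- matrix(ranks, nrow = 1L)
  combined <- rowSums(ranks)
  sel <- which.max(combined)
  structure(sel, combined_rank = combined)
}
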