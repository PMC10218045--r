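#' Group geometry: centroids and pooled covariance
#'
#' Computes, in whatever space the points live in (super scores or
#' Y-estimates), the per-group centroids, the per-group covariance matrices
#' and the pooled covariance
#' `S = ((n_1 - 1) S_1 + ... + (n_G - 1) S_G) / (n - G)`,
#' as used by the Mahalanobis decision rule. Groups with a single sample
#' contribute nothing to the pooled sum.
#'
#' @param points Numeric matrix, `n` samples by `d` dimensions.
#' @param labels Factor of group labels (length `n`).
#' @return An object of class `"group_geometry"`: `centroids` (`G` by `d`),
#'   `pooled_cov` (`d` by `d`), `group_covs` (list), `group_sizes`, `levels`.
#' @export
group_geometry <- function(points, labels) {
  points <- as.matrix(points)
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  G <- length(lev)
  if (G < 2L) stop("need at least two groups", call. = FALSE)
  n_g <- as.integer(table(labels))
  centroids <- rowsum(points, labels) / n_g
  d <- ncol(points)
  Sg <- vector("list", G)
  names(Sg) <- lev
  pooled <- matrix(0, d, d)
  for (g in seq_len(G)) {
    pts <- points[labels == lev[g], , drop = FALSE]
    if (n_g[g] >= 2L) {
      Sg[[g]] <- stats::cov(pts)
      pooled <- pooled + (n_g[g] - 1L) * Sg[[g]]
    } else {
      Sg[[g]] <- matrix(NA_real_, d, d)
    }
  }
  pooled <- pooled / (sum(n_g) - G)
  structure(list(centroids = centroids, pooled_cov = pooled,
                 group_covs = Sg, group_sizes = n_g, levels = lev),
            class = "group_geometry")
}

# argmin per row with ties going to the lowest group index
argmin_labels <- function(d2, levels) {
  idx <- apply(d2, 1L, which.min)
  factor(levels[idx], levels = levels)
}

#' Fixed-cutoff decision rule (binary)
#'
#' Y-estimates over 0.5 on the original indicator scale are assigned to the
#' group coded 1 (the second level); estimates of 0.5 or below to the group
#' coded 0.
#'
#' @param y_est Matrix (or vector) of Y-estimates with a single column. If
#'   `y_offset` is supplied the estimates are taken to be on the centered
#'   scale and are re-shifted first.
#' @param levels Character vector of the two group levels, in coding order
#'   (level 1 coded 0, level 2 coded 1).
#' @param y_offset Optional stored Y offset for re-shifting centered
#'   estimates.
#' @return Factor of predicted labels.
#' @export
classify_fixed_cutoff <- function(y_est, levels, y_offset = NULL) {
  y_est <- as.matrix(y_est)
  if (ncol(y_est) != 1L)
    stop("fixed cutoff applies to binary outcomes only (one Y column); got ",
         ncol(y_est), " columns", call. = FALSE)
  if (length(levels) != 2L)
    stop("fixed cutoff needs exactly two group levels", call. = FALSE)
  v <- drop(y_est)
  if (!is.null(y_offset)) v <- v + y_offset
  factor(ifelse(v > 0.5, levels[2L], levels[1L]), levels = levels)
}

#' Maximum-Y decision rule (multiclass)
#'
#' Each sample is assigned to the group whose Y-estimate column is largest;
#' ties go to the lowest group index.
#'
#' @param y_est Matrix of Y-estimates, `n` by `G` with `G >= 3`, on the
#'   indicator scale.
#' @param levels Group levels in column order; defaults to the column names.
#' @return Factor of predicted labels.
#' @export
classify_max_y <- function(y_est, levels = colnames(y_est)) {
  y_est <- as.matrix(y_est)
  if (ncol(y_est) < 3L)
    stop("Max Y applies to multiclass outcomes (G >= 3 columns)",
         call. = FALSE)
  idx <- apply(y_est, 1L, which.max)
  factor(levels[idx], levels = levels)
}

#' Euclidean-distance decision rule
#'
#' Assigns each point to the group with the nearest centroid in squared
#' Euclidean distance; ties go to the lowest group index.
#'
#' @param points Matrix of points (super scores or Y-estimates).
#' @param geometry A [group_geometry()] computed on training points in the
#'   same space.
#' @return Factor of predicted labels.
#' @export
classify_euclidean <- function(points, geometry) {
  stopifnot(inherits(geometry, "group_geometry"))
  points <- as.matrix(points)
  if (ncol(points) != ncol(geometry$centroids))
    stop("points have ", ncol(points), " dimensions but centroids have ",
         ncol(geometry$centroids), call. = FALSE)
  d2 <- vapply(seq_along(geometry$levels), function(g)
    rowSums(sweep(points, 2L, geometry$centroids[g, ], "-")^2),
    numeric(nrow(points)))
  if (nrow(points) == 1L) d2 <- matrix(d2, nrow = 1L)
  argmin_labels(d2, geometry$levels)
}

#' Mahalanobis-distance decision rule
#'
#' Assigns each point to the group with the smallest squared Mahalanobis
#' distance `(x - c_g) S^-1 (x - c_g)'` using the pooled covariance `S`.
#' Refuses if `S` is singular or ill-conditioned (condition number above
#' `max_condition`), in which case the Euclidean rule is the fallback to
#' reach for.
#'
#' @inheritParams classify_euclidean
#' @param max_condition Largest acceptable condition number of the pooled
#'   covariance.
#' @return Factor of predicted labels.
#' @export
classify_mahalanobis <- function(points, geometry, max_condition = 1e12) {
  stopifnot(inherits(geometry, "group_geometry"))
  points <- as.matrix(points)
  if (ncol(points) != ncol(geometry$centroids))
    stop("points have ", ncol(points), " dimensions but centroids have ",
         ncol(geometry$centroids), call. = FALSE)
  S <- geometry$pooled_cov
  sv <- tryCatch(svd(S, nu = 0, nv = 0)$d, error = function(e) 0)
  kap <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (!is.finite(kap) || kap > max_condition)
    stop("pooled covariance is singular or ill-conditioned (condition ",
         "number ", format(kap, digits = 3), "); consider the Euclidean ",
         "distance rule instead", call. = FALSE)
  Sinv <- solve(S)
  d2 <- vapply(seq_along(geometry$levels), function(g)
    stats::mahalanobis(points, geometry$centroids[g, ], Sinv,
                       inverted = TRUE),
    numeric(nrow(points)))
  if (nrow(points) == 1L) d2 <- matrix(d2, nrow = 1L)
  argmin_labels(d2, geometry$levels)
}

#' PCA + Mahalanobis decision rule (multiclass)
#'
#' Fits a principal component analysis on the training Y-estimates, projects
#' training and new estimates onto the first `G - 1` components, and applies
#' the Mahalanobis rule in that space with the pooled covariance recomputed
#' there.
#'
#' @param y_est New Y-estimates (`n_new` by `G`, `G >= 3`).
#' @param y_est_train Training Y-estimates (`n` by `G`).
#' @param labels Training group labels.
#' @param max_condition Passed to [classify_mahalanobis()].
#' @return Factor of predicted labels.
#' @export
classify_pca_md <- function(y_est, y_est_train, labels,
                            max_condition = 1e12) {
  y_est <- as.matrix(y_est)
  y_est_train <- as.matrix(y_est_train)
  labels <- droplevels(as.factor(labels))
  G <- length(levels(labels))
  if (G < 3L || ncol(y_est_train) < 3L)
    stop("PCA + MD applies to multiclass outcomes (G >= 3)", call. = FALSE)
  k <- G - 1L
  pca <- stats::prcomp(y_est_train, center = TRUE, scale. = FALSE)
  rank <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  if (rank < k)
    stop("training Y-estimates have rank ", rank, " < G - 1 = ", k,
         "; PCA projection undefined", call. = FALSE)
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  proj_train <- sweep(y_est_train, 2L, pca$center, "-") %*% rot
  proj_new <- sweep(y_est, 2L, pca$center, "-") %*% rot
  geom <- group_geometry(proj_train, labels)
  classify_mahalanobis(proj_new, geom, max_condition = max_condition)
}

#' Decision rules applicable to an outcome type
#'
#' @param outcome_type `"binary"` or `"multiclass"`.
#' @return Character vector of rule names: for binary outcomes
#'   `fixed_cutoff`, `ed_super`, `md_super`; for multiclass `max_y`,
#'   `ed_super`, `ed_y`, `md_super`, `pca_md`.
#' @export
applicable_rules <- function(outcome_type = c("binary", "multiclass")) {
  outcome_type <- match.arg(outcome_type)
  if (outcome_type == "binary") c("fixed_cutoff", "ed_super", "md_super")
  else c("max_y", "ed_super", "ed_y", "md_super", "pca_md")
}
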