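make_geometry <- function(centroids, pooled, levels, sizes = NULL) {
  structure(list(centroids = centroids, pooled_cov = pooled,
                 group_covs = NULL,
                 group_sizes = sizes %||% rep(10, length(levels)),
                 levels = levels),
            class = "group_geometry")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fixed cutoff thresholds re-shifted estimates at 0.5", {
  lev <- c("0", "1")
  expect_equal(as.character(classify_fixed_cutoff(c(0.7, 0.3), lev)),
               c("1", "0"))
  # the boundary value goes to group 0
  expect_equal(as.character(classify_fixed_cutoff(0.5, lev)), "0")
  # centered estimate 0 with the stored binary offset 0.5 is the boundary
  expect_equal(as.character(classify_fixed_cutoff(0, lev, y_offset = 0.5)),
               "0")
  expect_error(classify_fixed_cutoff(matrix(0, 2, 3), c("a", "b", "c")),
               "binary")
})

test_that("Max Y takes the row argmax with ties to the lowest index", {
  lev <- c("A", "B", "C")
  est <- rbind(c(0.1, 0.8, 0.1), c(0.4, 0.4, 0.2), c(0, 0, 1))
  colnames(est) <- lev
  expect_equal(as.character(classify_max_y(est)), c("B", "A", "C"))
  # permuting columns (with their labels) permutes assignments identically
  perm <- c(3, 1, 2)
  expect_equal(as.character(classify_max_y(est[, perm],
                                           levels = lev[perm])),
               as.character(classify_max_y(est)))
  expect_error(classify_max_y(matrix(0, 2, 1)), "multiclass")
})

test_that("Euclidean rule assigns the nearest centroid", {
  geom <- make_geometry(rbind(a = 0, b = 10), diag(1), c("a", "b"))
  expect_equal(as.character(classify_euclidean(matrix(4), geom)), "a")
  expect_equal(as.character(classify_euclidean(matrix(0), geom)), "a")
  # equidistant point goes to the lower-indexed group
  expect_equal(as.character(classify_euclidean(matrix(5), geom)), "a")
  expect_error(classify_euclidean(matrix(0, 1, 2), geom), "dimensions")
})

test_that("Mahalanobis with identity covariance equals Euclidean", {
  set.seed(30)
  cents <- matrix(rnorm(6), 3)
  geom <- make_geometry(cents, diag(2), c("A", "B", "C"))
  pts <- matrix(rnorm(2000), ncol = 2)
  expect_equal(classify_mahalanobis(pts, geom),
               classify_euclidean(pts, geom))
})

test_that("anisotropic pooled covariance reweights the axes", {
  # axis 2 has variance 100: a point far along axis 2 but near along
  # axis 1 is classified by axis-1 proximity
  geom <- make_geometry(rbind(A = c(0, 0), B = c(4, 20)),
                        diag(c(1, 100)), c("A", "B"))
  p <- matrix(c(0.5, 18), 1)
  # explicit distances: MD_A = 0.25 + 3.24, MD_B = 12.25 + 0.04
  expect_equal(
    drop(stats::mahalanobis(p, c(0, 0), diag(c(1, 100)))), 3.49)
  expect_equal(
    drop(stats::mahalanobis(p, c(4, 20), diag(c(1, 100)))), 12.29)
  expect_equal(as.character(classify_mahalanobis(p, geom)), "A")
  # Euclidean would follow the (long) second axis instead
  expect_equal(as.character(classify_euclidean(p, geom)), "B")
})

test_that("pooled covariance matches the hand-computed four-point toy", {
  pts <- rbind(c(0, 0), c(2, 2), c(4, 0), c(6, 2))
  lab <- factor(c("A", "A", "B", "B"))
  geom <- group_geometry(pts, lab)
  # S_A = S_B = [[2,2],[2,2]]; pooled = (1*S_A + 1*S_B) / (4 - 2)
  expect_equal(geom$pooled_cov, matrix(2, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(geom$centroids), rbind(c(1, 1), c(5, 1)))
})

test_that("singular pooled covariance is refused with advice", {
  pts <- cbind(rnorm(10), 0)  # second dimension constant
  geom <- group_geometry(pts, balanced_binary(10))
  expect_error(classify_mahalanobis(pts, geom), "Euclidean")
})

test_that("all rules are invariant to a constant shift", {
  set.seed(31)
  pts <- matrix(rnorm(60), ncol = 2)
  lab <- factor(rep(c("A", "B", "C"), each = 10))
  shift <- c(5, -3)
  pts2 <- sweep(pts, 2, shift, "+")
  g1 <- group_geometry(pts, lab)
  g2 <- group_geometry(pts2, lab)
  expect_equal(classify_euclidean(pts, g1), classify_euclidean(pts2, g2))
  expect_equal(classify_mahalanobis(pts, g1),
               classify_mahalanobis(pts2, g2))
})

test_that("PCA + MD uses G - 1 components and matches direct MD", {
  set.seed(32)
  n <- 45
  lab <- factor(rep(c("A", "B", "C"), each = 15))
  two_d <- matrix(rnorm(2 * n), n) +
    cbind(2 * (as.integer(lab) - 2), as.integer(lab))
  # three estimate columns with an exact affine dependency (rank 2)
  est <- cbind(two_d, 1 - two_d[, 1] - two_d[, 2])
  new_two <- matrix(rnorm(20), 10)
  new_est <- cbind(new_two, 1 - new_two[, 1] - new_two[, 2])
  got <- classify_pca_md(new_est, est, lab)
  # MD is invariant to invertible linear maps, so projecting onto the
  # first 2 PCs must agree with MD in the original 2-D coordinates
  direct <- classify_mahalanobis(new_two, group_geometry(two_d, lab))
  expect_equal(as.character(got), as.character(direct))

  # rank below G - 1 is refused
  flat <- tcrossprod(rnorm(n), c(1, 2, 3))
  expect_error(classify_pca_md(new_est, flat, lab), "rank")
  expect_error(classify_pca_md(matrix(0, 2, 2), matrix(0, 10, 2),
                               balanced_binary(10)), "multiclass")
})
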