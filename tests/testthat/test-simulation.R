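test_that("covariance construction honours the variances and repairs PD", {
  expect_equal(build_covariance(sqrt(3), 0.6, 0.9), matrix(3, 1, 1))
  set.seed(50)
  S0 <- build_covariance(rep(1, 8), 0, 0)
  expect_equal(S0, diag(8))
  S <- build_covariance(c(rep(1, 50), rep(sqrt(3), 50)), 0.6, 0.9)
  expect_equal(diag(S), c(rep(1, 50), rep(3, 50)), tolerance = 1e-8)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(build_covariance(c(1, -1), 0, 0.5), "positive")
})

test_that("structure maps satisfy their membership contracts", {
  set.seed(51)
  # cor: every relevant position holds a highly correlated column
  m_cor <- structure_map("cor", 100, 20, 10, 6)
  expect_true(all(m_cor[1:10] <= 20))
  expect_setequal(sort(m_cor), 1:100)
  # order: exactly the first n_high relevant positions are high
  m_ord <- structure_map("order", 100, 20, 10, 6)
  expect_true(all(m_ord[1:6] <= 20))
  expect_true(all(m_ord[7:10] > 20))
  # inverse: no relevant position is highly correlated
  m_inv <- structure_map("inverse", 100, 20, 10, 6)
  expect_true(all(m_inv[1:10] > 20))
  # random is a seeded permutation
  set.seed(52); a <- structure_map("random", 50, 10, 10, 6)
  set.seed(52); b <- structure_map("random", 50, 10, 10, 6)
  expect_identical(a, b)
  expect_setequal(a, 1:50)
  # infeasible: fewer high columns than relevant positions under cor
  expect_error(structure_map("cor", 100, 5, 10, 6), "infeasible")
})

test_that("simulated blocks match the stated moments", {
  scn <- simulation_scenario(n = 10000, q = 30, q_h = 10, p = 12, p_h = 5,
                             structure = "cor", r = 0, seed = 53)
  sim <- simulate_blocks(scn)
  expect_equal(dim(sim$X1), c(10000, 30))
  expect_equal(dim(sim$X2), c(10000, 12))
  # block-2 features: mean 5, variance 3
  expect_lt(max(abs(colMeans(sim$X2) - 5)), 3 * sqrt(3 / 10000) + 0.05)
  expect_lt(max(abs(apply(sim$X1, 2, var) - 1)), 0.2)
  # the highly correlated set of block 1 sits at the relevant positions
  # under "cor"; their average pairwise correlation reflects U(0.6, 0.9)
  high_cols <- which(sim$maps[[1]] <= scn$q_h)
  C <- cor(sim$X1[, high_cols])
  avg <- mean(C[upper.tri(C)])
  expect_gt(avg, 0.5)
  expect_lt(avg, 0.95)
})

test_that("binary outcome follows the logistic model", {
  set.seed(54)
  X1 <- matrix(rnorm(200 * 15), 200)
  X2 <- matrix(rnorm(200 * 8, 5, sqrt(3)), 200)
  zero_beta <- list(b1 = numeric(15), b2 = numeric(8))
  out <- simulate_binary_outcome(X1, X2, r = 0, beta = zero_beta)
  expect_true(all(out$prob == 0.5))
  # r = 0: the linear predictor is a deterministic function of X and beta
  out2 <- simulate_binary_outcome(X1, X2, r = 0, beta = zero_beta)
  expect_identical(out$eta, out2$eta)
  # saturation at a huge positive predictor
  big <- list(b1 = c(50, numeric(14)), b2 = numeric(8))
  out3 <- simulate_binary_outcome(X1, X2, r = 0, beta = big)
  expect_gt(mean(out3$prob[X1[, 1] > 1]), 0.999)
})

test_that("multiclass outcome is a softmax with a baseline class", {
  set.seed(55)
  X1 <- matrix(rnorm(300 * 15), 300)
  X2 <- matrix(rnorm(300 * 8, 5, sqrt(3)), 300)
  zero <- list(b1 = numeric(15), b2 = numeric(8))
  out <- simulate_multiclass_outcome(X1, X2, r = 0,
                                     beta = list(class2 = zero,
                                                 class3 = zero))
  expect_true(all(abs(out$prob - 1 / 3) < 1e-12))
  expect_equal(rowSums(out$prob), rep(1, 300))
  expect_equal(rowSums(out$Y), rep(1, 300), ignore_attr = TRUE)
  # class 1 is the zero-predictor baseline: with strong class-2 signal its
  # probability falls below 1/3 wherever that signal is positive
  b2 <- list(b1 = c(5, numeric(14)), b2 = numeric(8))
  out2 <- simulate_multiclass_outcome(X1, X2, r = 0,
                                      beta = list(class2 = b2,
                                                  class3 = zero))
  expect_true(all(out2$prob[X1[, 1] > 0.5, 1] < 1 / 3))
})

test_that("generate_scenario yields matched train/test with shared truth", {
  scn <- simulation_scenario(n = 40, q = 40, q_h = 15, p = 20, p_h = 6,
                             structure = "cor", r = 1, seed = 56)
  ds <- generate_scenario(scn)
  expect_equal(n_samples(ds$x), 40)
  expect_equal(n_samples(ds$x_test), 40)
  expect_equal(unname(block_sizes(ds$x)), c(40, 20))
  expect_equal(unname(block_sizes(ds$x_test)), c(40, 20))
  expect_equal(ds$truth, list(block1 = 1:10, block2 = 1:5))
  ds2 <- generate_scenario(scn)
  expect_identical(ds$x$blocks, ds2$x$blocks)
  expect_identical(ds$y, ds2$y)

  scn3 <- simulation_scenario(n = 45, q = 40, q_h = 15, p = 20, p_h = 6,
                              structure = "cor", r = 0,
                              outcome = "multiclass", seed = 57)
  ds3 <- generate_scenario(scn3)
  expect_equal(levels(ds3$y), c("G1", "G2", "G3"))
  expect_true(all(table(ds3$y) > 0))
})

test_that("higher noise lowers average test accuracy", {
  accs <- sapply(c(0, 5), function(r) {
    mean(sapply(1:20, function(i) {
      scn <- simulation_scenario(n = 60, q = 50, q_h = 15, p = 20, p_h = 6,
                                 structure = "cor", r = r,
                                 seed = 600 + i)
      ds <- generate_scenario(scn)
      fit <- asmbplsda(ds$x, ds$y, matrix(c(0.8, 0.7), 1, 2),
                       n_components = 1)
      mean(predict(fit, ds$x_test) == ds$y_test)
    }))
  })
  expect_gt(accs[1], accs[2])
})
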