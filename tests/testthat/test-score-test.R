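test_that("intercept-only null fit is the closed-form logistic MLE", {
  expect_equal(fit_null_intercept(c(1, 1, 0, 0)),
               list(mu0 = 0.5, beta0 = 0))
  f <- fit_null_intercept(c(1, 0, 0, 0))
  expect_equal(f$mu0, 0.25)
  expect_equal(f$beta0, log(1 / 3))   # iterative glm fit gives -1.09861229
  expect_error(fit_null_intercept(c(1, 1, 1, 1)), "degenerate")
  expect_error(fit_null_intercept(c(0, 0)), "degenerate")
  expect_error(fit_null_intercept(c(0, 2)), "0/1")
})

test_that("score quadratic form matches the explicit double sum", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(score_quadratic(K, c(1, 0)), 0.25)
  expect_equal(score_quadratic(diag(2), c(1, 0)), 0.5)
  expect_equal(score_quadratic(matrix(0, 3, 3), c(1, 0, 1),
                               null = list(mu0 = 2 / 3)), 0)
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    K <- gram_matrix(random_set(3, n), kernel_spec("distance", 2))
    mu0 <- mean(y)
    expect_equal(score_quadratic(K, y), quadratic_oracle(K, y, mu0))
    expect_gte(score_quadratic(K, y), -1e-10)   # PSD kernel
  }
  expect_error(score_quadratic(diag(3), c(1, 0)), "dimension")
})

test_that("null moments match the explicit centered-matrix algebra", {
  nm <- null_moments(diag(4), list(mu0 = 0.5))
  expect_equal(nm$mu_Q, 0.75)
  expect_equal(nm$sigma_Q, sqrt(2 * 0.0625 * 3))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    mu0 <- stats::runif(1, 0.2, 0.8)
    K <- gram_matrix(random_set(2, n), kernel_spec("distance", 3))
    got <- null_moments(K, list(mu0 = mu0))
    want <- moments_oracle(K, mu0)
    expect_equal(got$mu_Q, want$mu_Q)
    expect_equal(got$sigma_Q, want$sigma_Q)
  }
  # constant kernel: centering annihilates it
  expect_error(null_moments(matrix(0.8, 5, 5), list(mu0 = 0.5)),
               "uninformative")
})

test_that("null mean matches a Bernoulli relabeling oracle with refit intercept", {
  set.seed(12)
  n <- 6
  K <- gram_matrix(random_set(3, n, zero_prob = 0.3),
                   kernel_spec("distance", 2))
  mu0 <- 1 / 3
  nm <- null_moments(K, list(mu0 = mu0))
  B <- 1e5
  Y <- matrix(rbinom(n * B, 1, mu0), nrow = n)
  C <- sweep(Y, 2, colMeans(Y))
  Q <- colSums((K %*% C) * C)
  mc_se <- stats::sd(Q) / sqrt(B)
  expect_lt(abs(mean(Q) - nm$mu_Q), 3 * mc_se)
})

test_that("score profile standardises Q and is relabeling-invariant", {
  set.seed(13)
  X <- random_set(2, 12, zero_prob = 0.3)
  y <- rep(c(1, 0), 6)
  grid <- bandwidth_grid(0.1, 50, 25)
  prof <- score_profile(X, y, family = "distance", grid = grid)
  # definitional check at one bandwidth
  k <- 10
  K <- gram_matrix(X, kernel_spec("distance", prof$grid[k]))
  nm <- null_moments(K, fit_null_intercept(y))
  expect_equal(prof$scores[k],
               (score_quadratic(K, y) - nm$mu_Q) / nm$sigma_Q)
  expect_equal(prof$max_score, max(prof$scores))
  expect_equal(prof$total_variation, sum(abs(diff(prof$scores))))
  # joint sample permutation leaves the profile unchanged
  perm <- sample(12)
  prof2 <- score_profile(X[, perm], y[perm], family = "distance", grid = grid)
  expect_equal(prof2$scores, prof$scores)
  # swapping the 0/1 coding leaves Q and hence S unchanged
  prof3 <- score_profile(X, 1 - y, family = "distance", grid = grid)
  expect_equal(prof3$scores, prof$scores)
})

test_that("distance family equals plain Gaussian when nothing is absent", {
  set.seed(14)
  X <- random_set(4, 10, zero_prob = 0) + 0.1
  y <- rep(c(1, 0), 5)
  grid <- bandwidth_grid(0.5, 100, 40)
  a <- kernel_score_test(X, y, "distance", grid)
  b <- kernel_score_test(X, y, "gaussian", grid)
  expect_equal(a$scores, b$scores)
  expect_equal(a$p_upper, b$p_upper)
})

test_that("Davies bound matches hand-derived values and is capped", {
  expect_equal(davies_upper_bound(list(max_score = 1.6449,
                                       total_variation = 0)),
               stats::pnorm(-1.6449))
  expect_equal(davies_upper_bound(list(max_score = 2, total_variation = 1)),
               0.0497456152, tolerance = 1e-6)
  expect_equal(davies_upper_bound(list(max_score = 0, total_variation = 10)),
               1)
  expect_error(davies_upper_bound(list(max_score = NULL,
                                       total_variation = 1)), "profile")
})

test_that("strong separation is detected, and the bound exceeds a permutation p-value", {
  set.seed(15)
  X <- matrix(c(rnorm(10, 5, 0.2), rep(0, 10)), nrow = 1)
  y <- rep(c(1, 0), each = 10)
  for (fam in c("distance", "stratified")) {
    chk <- perm_sup_pvalue(X, y, fam, bandwidth_grid(0.1, 100, 30), B = 1000)
    expect_lt(chk$p_upper, 0.05)
    expect_lt(chk$p_perm, 0.005)
    expect_gte(chk$p_upper, chk$p_perm - 3 * chk$se)
  }
})

test_that("degenerate bandwidths are dropped; all-degenerate errors", {
  # constant columns: all kernels constant -> degenerate at every bandwidth
  Xc <- matrix(3, nrow = 2, ncol = 6)
  y6 <- rep(c(1, 0), 3)
  expect_error(score_profile(Xc, y6, "distance"), "degenerate")
  expect_error(null_moments(matrix(1, 6, 6), list(mu0 = 0.5)),
               "uninformative")
  X <- matrix(rep(c(1, 2), each = 6), nrow = 1)  # two clusters of x values
  r <- kernel_score_test(X, rep(c(1, 0), 6), "distance",
                         bandwidth_grid(0.1, 10, 10))
  expect_true(r$p_upper > 0 && r$p_upper <= 1)
})

test_that("bandwidth grid construction honours spacing and bounds", {
  g <- bandwidth_grid()
  expect_length(g, 200)
  expect_equal(g[1], 1e-3)
  expect_equal(g[200], 1e3)
  expect_equal(diff(range(diff(g))), 0, tolerance = 1e-9)   # linear
  gl <- bandwidth_grid(1e-3, 1e3, 7, spacing = "log")
  expect_equal(diff(range(diff(log(gl)))), 0, tolerance = 1e-9)
  expect_error(bandwidth_grid(2, 1), "lower")
})
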