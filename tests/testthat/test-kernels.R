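test_that("presence pattern flags nonzero coordinates", {
  expect_identical(presence_pattern(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_identical(presence_pattern(c(3.1, 0)), c(1L, 0L))
  expect_identical(presence_pattern(c(2.0, 0.5, 7.1)), c(1L, 1L, 1L))
  expect_error(presence_pattern(c(-1, 2)), "nonnegative")
  expect_error(presence_pattern(numeric(0)), "length")
})

test_that("presence-penalised distance matches its worked examples", {
  expect_equal(metabolite_distance(1, 2), 1)
  expect_equal(metabolite_distance(0, 1), sqrt(2))
  expect_equal(metabolite_distance(c(0, 2), c(1, 0)), sqrt(7))
  # identity of indiscernibles, any p
  for (p in c(1, 3, 6)) {
    x <- random_set(p, 1)[, 1]
    expect_equal(metabolite_distance(x, x), 0)
  }
  expect_error(metabolite_distance(c(1, 2), 1), "length")
})

test_that("distance is a metric on random triples", {
  set.seed(42)
  for (i in seq_len(10000)) {
    p <- sample(1:5, 1)
    x <- random_set(p, 1, zero_prob = 0.4)[, 1]
    y <- random_set(p, 1, zero_prob = 0.4)[, 1]
    z <- random_set(p, 1, zero_prob = 0.4)[, 1]
    dxy <- metabolite_distance(x, y)
    expect_identical(dxy, metabolite_distance(y, x))
    expect_gte(dxy, 0)
    expect_lte(metabolite_distance(x, z),
               dxy + metabolite_distance(y, z) + 1e-12)
  }
})

test_that("kernel values match worked scalar examples and bounds", {
  expect_equal(distance_kernel_value(0, 1, rho = 2), exp(-1))
  expect_equal(distance_kernel_value(c(1, 2), c(1, 2), 5), 1)
  expect_equal(gaussian_kernel_value(0, 1, 1), exp(-1))
  expect_equal(gaussian_kernel_value(c(1, 3), c(1, 3), 0.1), 1)
  expect_equal(stratified_kernel_value(c(1, 0), c(0, 1), 1), 0)
  expect_equal(stratified_kernel_value(c(1, 2), c(2, 2), 1), exp(-1))
  expect_equal(stratified_kernel_value(c(1, 2), c(1, 2), 3), 1)
  expect_error(distance_kernel_value(0, 1, rho = 0), "positive")
  expect_error(stratified_kernel_value(0, 1, rho = -1), "positive")
})

test_that("distance kernel increases with bandwidth and is dominated by the Gaussian", {
  x <- c(0, 2, 3)
  y <- c(1, 2, 0)
  rhos <- c(0.5, 1, 2, 8)
  v <- vapply(rhos, function(r) distance_kernel_value(x, y, r), 1)
  expect_true(all(diff(v) > 0))
  for (r in rhos) {
    # presence penalty > 0 here: strict domination
    expect_lt(distance_kernel_value(x, y, r), gaussian_kernel_value(x, y, r))
    # matching patterns: equality
    expect_equal(distance_kernel_value(c(1, 2), c(3, 4), r),
                 gaussian_kernel_value(c(1, 2), c(3, 4), r))
  }
})

test_that("Gram matrices are symmetric, unit-diagonal, in [0,1], and PSD", {
  set.seed(7)
  for (i in seq_len(25)) {
    n <- sample(5:50, 1)
    p <- sample(1:8, 1)
    X <- random_set(p, n, zero_prob = stats::runif(1, 0, 0.6))
    for (fam in c("distance", "stratified", "gaussian")) {
      K <- gram_matrix(X, kernel_spec(fam, bandwidth = stats::runif(1, 0.5, 5)))
      expect_identical(K, t(K))
      expect_equal(unname(diag(K)), rep(1, n))
      expect_true(all(K >= 0 & K <= 1))
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("gram_matrix reproduces elementwise kernel evaluations", {
  set.seed(8)
  X <- random_set(3, 6, zero_prob = 0.4)
  for (fam in c("distance", "stratified", "gaussian")) {
    K <- gram_matrix(X, kernel_spec(fam, 1.7))
    f <- switch(fam, distance = distance_kernel_value,
                stratified = stratified_kernel_value,
                gaussian = gaussian_kernel_value)
    for (i in 1:6) {
      for (j in 1:6) {
        expect_equal(K[i, j], f(X[, i], X[, j], 1.7), tolerance = 1e-12)
      }
    }
  }
  # two samples, p = 1, worked example
  K2 <- gram_matrix(matrix(c(0, 1), nrow = 1), kernel_spec("distance", 2))
  expect_equal(K2[1, 2], exp(-1))
})

test_that("stratified Gram is zero across strata and Gaussian within", {
  set.seed(9)
  X <- random_set(4, 30, zero_prob = 0.5)
  K <- gram_matrix(X, kernel_spec("stratified", 2))
  pat <- apply(X != 0, 2, paste, collapse = "")
  same <- outer(pat, pat, "==")
  expect_true(all(K[!same] == 0))
  for (s in unique(pat)) {
    idx <- which(pat == s)
    if (length(idx) >= 2) {
      expect_equal(K[idx, idx],
                   gram_matrix(X[, idx, drop = FALSE],
                               kernel_spec("gaussian", 2)))
    }
  }
})

test_that("per-feature normalisation rescales nonzero entries only", {
  X <- rbind(c(0, 2, 4, 6), c(1, 1, 1, 1))
  N <- normalize_nonzero(X)
  expect_equal(N[1, 1], 0)
  expect_equal(N[1, -1], X[1, -1] / stats::sd(c(2, 4, 6)))
  expect_equal(N[2, ], X[2, ])   # zero variance: untouched
})
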