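# Shared fixtures and independent oracles.

# random zero-inflated measurement vectors (features x samples)
random_set <- function(p, n, zero_prob = 0.3, scale = 3) {
  X <- matrix(stats::rexp(p * n, rate = 1 / scale), nrow = p)
  X[stats::runif(p * n) < zero_prob] <- 0
  X
}

# blocks of near-duplicate features (within-block correlation ~ 1)
planted_blocks <- function(n_blocks = 3, block_size = 4, n_samples = 40,
                           noise = 0.02) {
  X <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    base <- stats::rnorm(n_samples)
    t(replicate(block_size, base + stats::rnorm(n_samples, sd = noise)))
  }))
  rownames(X) <- paste0("f", seq_len(nrow(X)))
  X
}

# brute-force distance oracle: term-by-term sum over coordinates
distance_oracle <- function(x, y) {
  pen <- sum((x != 0) != (y != 0))
  sqrt(pen + sum((x - y)^2))
}

# brute-force quadratic form oracle: explicit double sum
quadratic_oracle <- function(K, y, mu0) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + K[i, j] * (y[i] - mu0) * (y[j] - mu0)
    }
  }
  total
}

# explicit-matrix oracle for the null moments: materialise A = HKH
moments_oracle <- function(K, mu0) {
  n <- nrow(K)
  H <- diag(n) - matrix(1, n, n) / n
  A <- H %*% K %*% H
  v <- mu0 * (1 - mu0)
  list(mu_Q = v * sum(diag(A)),
       sigma_Q = sqrt(2 * v^2 * sum(diag(A %*% A))))
}

# Monte-Carlo permutation p-value of the sup-score statistic for one dataset,
# sharing only the Gram construction with the implementation (Q per
# permutation is recomputed directly from the kernel matrices).
perm_sup_pvalue <- function(X, y, family, grid = bandwidth_grid(), B = 2000) {
  obs <- kernel_score_test(X, y, family = family, grid = grid)
  n <- length(y)
  mu0 <- mean(y)
  rho <- obs$grid
  Kmats <- lapply(rho, function(r) gram_matrix(X, kernel_spec(family, r)))
  mom <- lapply(Kmats, null_moments, null = list(mu0 = mu0))
  Yp <- replicate(B, sample(y))          # n x B permuted labels
  C <- Yp - mu0
  sup <- rep(-Inf, B)
  for (k in seq_along(rho)) {
    q <- colSums((Kmats[[k]] %*% C) * C)
    s <- (q - mom[[k]]$mu_Q) / mom[[k]]$sigma_Q
    sup <- pmax(sup, s)
  }
  p <- mean(sup >= obs$max_score)
  list(p_perm = p, se = sqrt(p * (1 - p) / B), p_upper = obs$p_upper,
       max_score = obs$max_score)
}
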