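# Kernel-machine score test for a binary group effect.
#
# Model: logit Pr(y_i = 1) = beta0 + f(x_i), with f in the RKHS of the chosen
# kernel.  The null H0: f = 0 is tested with the quadratic score statistic
# Q(rho) = (y - mu0)' K(rho) (y - mu0), standardised by its null moments and
# maximised over a bandwidth grid; significance uses a Davies-type upper
# bound on the p-value of the supremum, since the bandwidth rho is a nuisance
# parameter that vanishes under the null.

#' Bandwidth grid for the sup-score test
#'
#' @param lower,upper Positive grid endpoints, `lower < upper`.  Defaults
#'   `1e-3` and `1e3`.
#' @param count Number of grid points (>= 2), default 200.
#' @param spacing `"linear"` (evenly spaced, the default) or `"log"`
#'   (evenly spaced on log scale).
#' @return An object of class `bandwidth_grid`: the vector of bandwidths with
#'   the construction parameters attached.
#' @export
bandwidth_grid <- function(lower = 1e-3, upper = 1e3, count = 200L,
                           spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!(lower > 0 && upper > lower)) stop("need 0 < lower < upper")
  count <- as.integer(count)
  if (count < 2L) stop("grid needs at least 2 points")
  rho <- switch(spacing,
    linear = seq(lower, upper, length.out = count),
    log = exp(seq(log(lower), log(upper), length.out = count)))
  structure(rho, lower = lower, upper = upper, count = count,
            spacing = spacing, class = c("bandwidth_grid", "numeric"))
}

#' Null (intercept-only) logistic fit
#'
#' For an intercept-only logistic regression the maximum-likelihood mean is
#' the sample proportion of cases; the intercept is its logit.
#'
#' @param y 0/1 group labels with both classes present.
#' @return List with `mu0` (fitted null mean) and `beta0` (intercept).
#' @export
fit_null_intercept <- function(y) {
  y <- check_labels(y)
  mu0 <- mean(y)
  list(mu0 = mu0, beta0 = log(mu0 / (1 - mu0)))
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate null fit: labels must contain both classes")
  }
  y
}

#' Kernel score quadratic form
#'
#' `Q = (y - mu0 1)' K (y - mu0 1)`, nonnegative for positive semidefinite K.
#'
#' @param K Symmetric `n x n` Gram matrix.
#' @param y 0/1 labels of length n.
#' @param null Null fit from [fit_null_intercept()] (defaults to fitting `y`).
#' @return A single nonnegative number.
#' @export
score_quadratic <- function(K, y, null = fit_null_intercept(y)) {
  K <- as.matrix(K)
  y <- as.numeric(y)
  if (nrow(K) != ncol(K) || length(y) != nrow(K)) {
    stop("dimension mismatch between K and y")
  }
  c0 <- y - null$mu0
  drop(crossprod(c0, K %*% c0))
}

#' Null mean and standard deviation of the score quadratic form
#'
#' Under the intercept-only null with a Gaussian working model the quadratic
#' form `Q` has mean `v * tr(A)` and variance `2 v^2 * tr(A^2)`, where
#' `v = mu0 (1 - mu0)` and `A = H K H` with the centering projection
#' `H = I - 11'/n` (centering reflects the estimated intercept).  The traces
#' are evaluated in closed form without materialising `A`.
#'
#' @inheritParams score_quadratic
#' @return List with `mu_Q` and `sigma_Q` (`sigma_Q > 0` required downstream;
#'   a constant kernel gives `sigma_Q = 0` and an error).
#' @export
null_moments <- function(K, null) {
  K <- as.matrix(K)
  n <- nrow(K)
  v <- null$mu0 * (1 - null$mu0)
  u <- colSums(K)
  s <- sum(u)
  trA <- sum(diag(K)) - s / n
  trA2 <- sum(K^2) - 2 * sum(u^2) / n + s^2 / n^2
  trA2 <- max(trA2, 0)
  sigma <- sqrt(2 * v^2 * trA2)
  # relative test: a constant kernel gives trA2 = 0 up to cancellation error
  if (trA2 <= sum(K^2) * 1e-12) {
    stop("uninformative kernel at this bandwidth (sigma_Q = 0)")
  }
  list(mu_Q = v * trA, sigma_Q = sigma)
}

# Vectorised engine: standardised scores S(rho) over a whole bandwidth grid
# for one feature-set.  Returns kept bandwidths, scores, raw Q values and the
# per-bandwidth null moments.  Grid points with sigma_Q ~ 0 are dropped.
score_profile_engine <- function(X, y, family, grid) {
  X <- as_set_matrix(X)
  y <- check_labels(y)
  n <- ncol(X)
  if (length(y) != n) stop("labels do not match the number of samples")
  rho <- as.numeric(grid)

  D <- pairwise_sqdist(X)
  mask <- NULL
  if (family == "distance") {
    D <- D + pairwise_presence_mismatch(X)
  } else if (family == "stratified") {
    mask <- (pairwise_presence_mismatch(X) == 0) * 1
  }

  # n^2 x m matrix of Gram entries, one column per bandwidth
  Kflat <- exp(outer(as.vector(D), 1 / rho, "*") * -1)
  if (!is.null(mask)) Kflat <- Kflat * as.vector(mask)
  diag_idx <- seq(1L, n * n, by = n + 1L)
  Kflat[diag_idx, ] <- 1

  mu0 <- mean(y)
  v <- mu0 * (1 - mu0)
  # closed-form traces of A = HKH and A^2 per bandwidth
  U <- matrix(colSums(array(Kflat, dim = c(n, n * length(rho)))),
              nrow = n)                       # column sums of K per rho
  s <- colSums(U)
  trK <- colSums(Kflat[diag_idx, , drop = FALSE])
  trA <- trK - s / n
  trA2 <- pmax(colSums(Kflat^2) - 2 * colSums(U^2) / n + s^2 / n^2, 0)
  mu_Q <- v * trA
  sigma_Q <- sqrt(2 * v^2 * trA2)

  c0 <- y - mu0
  Q <- drop(crossprod(as.vector(outer(c0, c0)), Kflat))

  keep <- trA2 > colSums(Kflat^2) * 1e-12
  if (!any(keep)) stop("all bandwidth grid points are degenerate")
  list(rho = rho[keep], scores = (Q[keep] - mu_Q[keep]) / sigma_Q[keep],
       q = Q[keep], mu_Q = mu_Q[keep], sigma_Q = sigma_Q[keep],
       n_dropped = sum(!keep))
}

#' Standardised score profile over a bandwidth grid
#'
#' Evaluates `S(rho) = (Q(rho) - mu_Q(rho)) / sigma_Q(rho)` at every grid
#' bandwidth for one feature-set.  Grid points whose kernel is uninformative
#' (null standard deviation numerically zero, e.g. a constant Gram matrix)
#' are dropped from the profile; the number dropped is recorded.
#'
#' @param X Feature-set matrix, features x samples (vector = one feature).
#' @param y 0/1 group labels, one per sample.
#' @param family Kernel family: `"distance"`, `"stratified"` or `"gaussian"`.
#' @param grid A [bandwidth_grid()].
#' @return An object of class `kernel_score_test` without the p-value bound:
#'   components `grid`, `scores`, `q_values`, `max_score`, `total_variation`,
#'   `family`, `n_dropped`.
#' @export
score_profile <- function(X, y,
                          family = c("distance", "stratified", "gaussian"),
                          grid = bandwidth_grid()) {
  family <- match.arg(family)
  eng <- score_profile_engine(X, y, family, grid)
  structure(list(
    grid = eng$rho,
    scores = eng$scores,
    q_values = eng$q,
    max_score = max(eng$scores),
    total_variation = sum(abs(diff(eng$scores))),
    p_upper = NA_real_,
    family = family,
    n_dropped = eng$n_dropped,
    grid_spec = attributes(grid)[c("lower", "upper", "count", "spacing")]
  ), class = "kernel_score_test")
}

#' Davies-type upper bound for the sup-score p-value
#'
#' For a supremum statistic `M = sup S(rho)` whose nuisance parameter `rho`
#' disappears under the null, the p-value is bounded by
#' \deqn{\Phi(-M) + V \exp(-M^2/2) / \sqrt{8\pi},}
#' where `V` is the total variation of the score profile over the grid.  The
#' bound is capped at 1.  (The decaying exponent `-M^2/2` is the Davies form;
#' with a growing exponent the bound would diverge for large `M` and be
#' useless.)
#'
#' @param result A `kernel_score_test` (from [score_profile()]), or a list
#'   with `max_score` and `total_variation`.
#' @return The p-value upper bound in (0, 1].
#' @export
davies_upper_bound <- function(result) {
  M <- result$max_score
  V <- result$total_variation
  if (is.null(M) || !is.finite(M)) stop("empty or invalid score profile")
  p <- stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)
  min(1, p)
}

#' Kernel score test for one feature-set
#'
#' End-to-end test of H0: no group effect, for one feature-set: builds the
#' Gram matrix at every grid bandwidth, standardises the score statistic,
#' takes the supremum, and bounds its p-value from above.
#'
#' @inheritParams score_profile
#' @return An object of class `kernel_score_test`: the score profile plus
#'   `max_score` (M), `total_variation` (V) and `p_upper`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(c(rep(0, 10), rnorm(10, 5, 0.3)), nrow = 1)
#' y <- rep(c(0, 1), each = 10)
#' kernel_score_test(X, y, family = "distance")$p_upper
kernel_score_test <- function(X, y,
                              family = c("distance", "stratified", "gaussian"),
                              grid = bandwidth_grid()) {
  res <- score_profile(X, y, family = family, grid = grid)
  res$p_upper <- davies_upper_bound(res)
  res
}

#' @export
print.kernel_score_test <- function(x, ...) {
  cat("Kernel score test (", x$family, " kernel)\n", sep = "")
  cat(sprintf("  grid: %d bandwidths in [%g, %g] (%s)%s\n",
              length(x$grid), min(x$grid), max(x$grid),
              x$grid_spec$spacing %||% "linear",
              if (x$n_dropped > 0)
                sprintf(", %d degenerate points dropped", x$n_dropped)
              else ""))
  cat(sprintf("  M = %.4f   V = %.4f   p_upper %s\n", x$max_score,
              x$total_variation,
              if (is.na(x$p_upper)) "= NA" else sprintf("= %.6g", x$p_upper)))
  invisible(x)
}
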