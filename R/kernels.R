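# Kernels for semicontinuous (zero-inflated) metabolite-set measurements.
#
# A measurement of a p-metabolite set is a vector in (R+ U {0})^p: an entry of
# 0 means the metabolite was not detected in that sample, a positive entry is
# its abundance.  Both kernels below are bounded in [0, 1] and positive
# definite, so they can serve as the similarity matrix of a kernel-machine
# score test.

#' Presence pattern of a measurement vector
#'
#' Returns the binary presence/absence indicator of each metabolite in a
#' measurement: 1 where the abundance is nonzero, 0 where it is absent.  The
#' `2^p` distinct patterns index the strata used by the stratified kernel,
#' from the all-absent stratum to the all-present one.
#'
#' @param x Numeric vector of nonnegative abundances (0 = absent).
#' @return Integer vector of 0/1 of the same length as `x`.
#' @seealso [stratified_kernel_value()]
#' @export
#' @examples
#' presence_pattern(c(3.1, 0))   # first metabolite present only
presence_pattern <- function(x) {
  x <- check_measurement(x)
  as.integer(x != 0)
}

check_measurement <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("measurement must have length >= 1")
  if (anyNA(x)) stop("measurement contains NA")
  if (any(x < 0)) stop("abundances must be nonnegative (0 encodes absence)")
  x
}

check_pair <- function(x, y) {
  x <- check_measurement(x)
  y <- check_measurement(y)
  if (length(x) != length(y)) stop("measurement vectors differ in length")
  list(x = x, y = y)
}

check_bandwidth <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho <= 0) {
    stop("bandwidth rho must be a single positive number")
  }
  as.numeric(rho)
}

#' Presence-penalised distance between two measurements
#'
#' The squared distance is the squared Euclidean distance between the
#' abundance vectors plus, for each coordinate, a unit penalty whenever one
#' measurement has the metabolite present and the other has it absent:
#' \deqn{d(x,y) = \sqrt{\sum_i I[\delta_{x_i} \neq \delta_{y_i}]
#'                     + \sum_i (x_i - y_i)^2},}
#' where \eqn{\delta_{x_i} = I[x_i \neq 0]}.  The penalty term carries the
#' discrete presence/absence information, the Euclidean term the continuous
#' abundance information.  This is a metric on the semicontinuous sample
#' space: symmetric, zero exactly at `x == y`, and satisfying the triangle
#' inequality.
#'
#' @param x,y Numeric vectors of equal length, nonnegative, 0 = absent.
#' @return A single nonnegative number.
#' @export
#' @examples
#' metabolite_distance(1, 2)  # both present: plain Euclidean, = 1
#' metabolite_distance(0, 1)  # absence penalty: sqrt(2)
metabolite_distance <- function(x, y) {
  v <- check_pair(x, y)
  sqrt(metabolite_distance2(v$x, v$y))
}

# squared distance, no validation (hot path)
metabolite_distance2 <- function(x, y) {
  sum((x != 0) != (y != 0)) + sum((x - y)^2)
}

#' Distance-based kernel
#'
#' `exp(-d^2(x, y) / rho)` with `d` the presence-penalised distance of
#' [metabolite_distance()].  Values lie in (0, 1] with 1 exactly at `x == y`.
#' When both vectors share a presence pattern the penalty vanishes and the
#' value equals the Gaussian kernel.
#'
#' @inheritParams metabolite_distance
#' @param rho Positive bandwidth.
#' @return Kernel value in (0, 1].
#' @export
distance_kernel_value <- function(x, y, rho) {
  v <- check_pair(x, y)
  rho <- check_bandwidth(rho)
  exp(-metabolite_distance2(v$x, v$y) / rho)
}

#' Stratified kernel
#'
#' The sample space is partitioned into `2^p` strata by presence pattern.
#' Two measurements in different strata have kernel value 0; within a stratum
#' the Gaussian kernel `exp(-||x - y||^2 / rho)` is used.  The Gaussian is
#' evaluated on the full p-vector: within a stratum the zero coordinates are
#' shared, so they contribute nothing to the sum and this equals the Gaussian
#' on the present coordinates.
#'
#' @inheritParams distance_kernel_value
#' @return Kernel value in \[0, 1\].
#' @export
stratified_kernel_value <- function(x, y, rho) {
  v <- check_pair(x, y)
  rho <- check_bandwidth(rho)
  if (any((v$x != 0) != (v$y != 0))) return(0)
  exp(-sum((v$x - v$y)^2) / rho)
}

#' Gaussian kernel
#'
#' `exp(-||x - y||^2 / rho)`, the standard squared-exponential kernel.
#'
#' @inheritParams distance_kernel_value
#' @return Kernel value in (0, 1].
#' @export
gaussian_kernel_value <- function(x, y, rho) {
  v <- check_pair(x, y)
  rho <- check_bandwidth(rho)
  exp(-sum((v$x - v$y)^2) / rho)
}

#' Kernel specification
#'
#' @param family One of `"distance"`, `"stratified"`, `"gaussian"`.
#' @param bandwidth Positive bandwidth `rho`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("distance", "stratified", "gaussian"),
                        bandwidth = 1) {
  family <- match.arg(family)
  bandwidth <- check_bandwidth(bandwidth)
  structure(list(family = family, bandwidth = bandwidth),
            class = "kernel_spec")
}

# Pairwise squared-distance building blocks for an n-sample set.
# X is a p x n matrix (features x samples).  Returns the n x n matrix of
# squared Euclidean distances between sample columns.
pairwise_sqdist <- function(X) {
  X <- as.matrix(X)
  cp <- crossprod(X)            # n x n inner products
  sq <- diag(cp)
  D <- outer(sq, sq, "+") - 2 * cp
  D[D < 0] <- 0                 # numerical noise
  D
}

# n x n count of presence-pattern mismatches between sample columns.
pairwise_presence_mismatch <- function(X) {
  P <- (as.matrix(X) != 0) * 1
  p <- nrow(P)
  # mismatches = #present_i + #present_j - 2 * #jointly_present
  joint <- crossprod(P)
  np <- diag(joint)
  outer(np, np, "+") - 2 * joint
}

#' Gram matrix of a metabolite-set over samples
#'
#' Builds the `n x n` similarity matrix between samples for one feature-set,
#' using the distance-based, stratified, or plain Gaussian kernel.  The
#' result is symmetric with unit diagonal and (numerically) positive
#' semidefinite.
#'
#' @param X Numeric matrix, features (rows) by samples (columns); a vector is
#'   treated as a single-feature set.  All entries nonnegative, 0 = absent.
#' @param spec A [kernel_spec()], or a family name (then `bandwidth` applies).
#' @param bandwidth Bandwidth used when `spec` is given as a family name.
#' @return An `n x n` numeric matrix with `dimnames` taken from the sample
#'   columns of `X`.
#' @export
#' @examples
#' X <- rbind(c(0, 1), c(2, 2))           # 2 features, 2 samples
#' gram_matrix(X, kernel_spec("distance", bandwidth = 2))
gram_matrix <- function(X, spec = kernel_spec(), bandwidth = NULL) {
  if (is.character(spec)) spec <- kernel_spec(spec, bandwidth %||% 1)
  stopifnot(inherits(spec, "kernel_spec"))
  X <- as_set_matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 samples for a Gram matrix")
  D <- pairwise_sqdist(X)
  K <- switch(spec$family,
    gaussian = exp(-D / spec$bandwidth),
    distance = exp(-(D + pairwise_presence_mismatch(X)) / spec$bandwidth),
    stratified = {
      mism <- pairwise_presence_mismatch(X)
      (mism == 0) * exp(-D / spec$bandwidth)
    })
  diag(K) <- 1
  dimnames(K) <- list(colnames(X), colnames(X))
  K
}

# coerce a set to a features x samples matrix and validate entries
as_set_matrix <- function(X) {
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("abundance matrix contains NA")
  if (any(X < 0)) stop("abundances must be nonnegative (0 encodes absence)")
  X
}

#' Per-feature normalisation of nonzero abundances
#'
#' Divides the nonzero entries of each feature row by the standard deviation
#' of that feature's nonzero entries, leaving zeros (absences) untouched.
#' Useful when abundances are large, so that the continuous term does not
#' swamp the presence penalty in the distance-based kernel.  Off by default
#' everywhere in this package.
#'
#' @param X Features-by-samples nonnegative matrix.
#' @return Matrix of the same shape.
#' @export
normalize_nonzero <- function(X) {
  X <- as_set_matrix(X)
  for (i in seq_len(nrow(X))) {
    nz <- X[i, ] != 0
    if (sum(nz) >= 2L) {
      s <- stats::sd(X[i, nz])
      if (s > 0) X[i, nz] <- X[i, nz] / s
    }
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
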