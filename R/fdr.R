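# Multiple-testing machinery: Storey-style pi0 and FDR estimation over the
# per-set p-values, a Bonferroni FWER variant, and true-false-discovery-
# proportion rejection counting for simulations with known ground truth.

check_pvalues <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  p
}

#' Estimate the proportion of true nulls (pi0)
#'
#' Storey's estimator: the p-value mass above the tuning point `lambda`,
#' rescaled by its expected value under uniformity and truncated at 1,
#' \deqn{\hat\pi_0(\lambda) = \#\{p_i > \lambda\} / (M (1-\lambda)).}
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param lambda Tuning value in (0, 1); default 0.7.
#' @return Estimated pi0 in \[0, 1\].
#' @export
estimate_pi0 <- function(p, lambda = 0.7) {
  p <- check_pvalues(p)
  if (!(is.numeric(lambda) && length(lambda) == 1L &&
        lambda > 0 && lambda < 1)) {
    stop("lambda must lie in (0, 1)")
  }
  min(1, sum(p > lambda) / (length(p) * (1 - lambda)))
}

#' Estimated FDR at a p-value cutoff
#'
#' \deqn{\widehat{FDR}(c) = M \hat\pi_0 c / \#\{p_i \le c\}.}  Returns `NA`
#' (a "no rejections" sentinel) when no p-value falls at or below `c`.
#'
#' @inheritParams estimate_pi0
#' @param cutoff Rejection cutoff `c` in (0, 1): reject when `p <= c`.
#' @param pi0 Proportion of true nulls in (0, 1\]; default estimated from `p`
#'   at `lambda`.
#' @return Estimated FDR (nonnegative), or `NA` if there are no rejections.
#' @export
estimate_fdr <- function(p, cutoff, pi0 = estimate_pi0(p, lambda),
                         lambda = 0.7) {
  p <- check_pvalues(p)
  stopifnot(cutoff > 0, cutoff < 1, pi0 > 0, pi0 <= 1)
  r <- sum(p <= cutoff)
  if (r == 0L) return(NA_real_)
  length(p) * pi0 * cutoff / r
}

#' Rejections-versus-estimated-FDR curve
#'
#' For a grid of cutoffs `c`, counts rejections `#{p <= c}` and estimates the
#' FDR at each cutoff with a single pi0 estimated at `lambda`.  Cutoffs with
#' zero rejections carry `fdr_hat = NA`.
#'
#' @inheritParams estimate_pi0
#' @param cutoffs Increasing cutoff values; default 100 points in (0, 0.05].
#' @return A data.frame with columns `cutoff`, `rejections`, `fdr_hat`, and
#'   attributes `pi0` and `lambda`.
#' @export
significance_vs_fdr_curve <- function(p, lambda = 0.7,
                                      cutoffs = seq(5e-4, 0.05,
                                                    length.out = 100)) {
  p <- check_pvalues(p)
  pi0 <- estimate_pi0(p, lambda)
  rej <- vapply(cutoffs, function(c) sum(p <= c), 1L)
  fdr <- ifelse(rej > 0, length(p) * pi0 * cutoffs / pmax(rej, 1L), NA_real_)
  out <- data.frame(cutoff = cutoffs, rejections = rej, fdr_hat = fdr)
  attr(out, "pi0") <- pi0
  attr(out, "lambda") <- lambda
  out
}

#' Bonferroni family-wise rejections
#'
#' Counts tests with `p < alpha / M` (strict).
#'
#' @inheritParams estimate_pi0
#' @param alpha Family-wise error level in (0, 1).
#' @return Integer count of rejections.
#' @export
bonferroni_rejections <- function(p, alpha = 0.05) {
  p <- check_pvalues(p)
  stopifnot(alpha > 0, alpha < 1)
  sum(p < alpha / length(p))
}

#' Rejection count at a true false-discovery-proportion level
#'
#' In simulations the ground truth is known, so the realised false-discovery
#' proportion (FDP) of any rejection region `[0, c]` can be computed exactly.
#' This returns the largest rejection count over cutoffs placed at the
#' observed p-values whose FDP (true nulls rejected / total rejected) is at
#' most `level`.  Tied p-values are rejected together.  If no nonempty
#' rejection set qualifies, the count is 0 with attribute
#' `attr(, "unattainable") = TRUE`.
#'
#' @inheritParams estimate_pi0
#' @param truth Logical vector, `TRUE` for truly differential (alternative)
#'   hypotheses, `FALSE` for true nulls.
#' @param level Maximum tolerated FDP, default 0.05.
#' @return Integer count, with logical attribute `unattainable`.
#' @export
true_fdp_rejections <- function(p, truth, level = 0.05) {
  p <- check_pvalues(p)
  if (missing(truth) || is.null(truth)) stop("truth flags are required")
  truth <- as.logical(truth)
  if (length(truth) != length(p) || anyNA(truth)) {
    stop("truth flags must be logical and match the p-values")
  }
  o <- order(p)
  ps <- p[o]
  false_rej <- cumsum(!truth[o])
  # rejection regions must respect ties: only cutoffs at the last index of
  # each distinct p-value are realisable as {p <= c}
  last_of_tie <- c(ps[-1] != ps[-length(ps)], TRUE)
  k <- seq_along(ps)
  ok <- last_of_tie & (false_rej / k <= level)
  if (!any(ok)) {
    return(structure(0L, unattainable = TRUE))
  }
  structure(max(k[ok]), unattainable = FALSE)
}

#' Uniformity diagnostic for null p-values
#'
#' The Storey FDR estimate assumes the true-null p-values are roughly
#' uniform.  As a diagnostic, this applies a one-sample Kolmogorov-Smirnov
#' test of uniformity to the p-values above 0.05 (rescaled to (0,1)), where
#' alternatives should be rare.  Reported, never enforced.
#'
#' @inheritParams estimate_pi0
#' @return List with `statistic`, `p_value`, and `n_used`.
#' @export
null_uniformity_diagnostic <- function(p) {
  p <- check_pvalues(p)
  tail_p <- p[p > 0.05]
  if (length(tail_p) < 5L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_used = length(tail_p)))
  }
  rescaled <- (tail_p - 0.05) / 0.95
  ks <- suppressWarnings(stats::ks.test(rescaled, "punif"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_used = length(tail_p))
}
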