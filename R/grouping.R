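# Feature-set formation: connected components of the thresholded
# absolute-correlation network.  Features that are (transitively) linked by
# a pairwise |correlation| above the threshold form one feature-set; pairwise
# all-vs-all correlation within a set is deliberately NOT required, since in
# a metabolic pathway every feature need only be strongly correlated with
# some other member, not with all of them.

#' Pairwise feature correlations
#'
#' Correlation between every pair of feature rows across samples.  Zeros are
#' included as values by default (absence is informative); optionally the
#' correlation of a pair can be restricted to samples where both features are
#' present.  Constant (zero-variance) features get correlation 0 with every
#' other feature, so they can never be linked.
#'
#' @param X Features-by-samples numeric matrix (>= 3 samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param jointly_present If `TRUE`, each pair's correlation uses only samples
#'   where both entries are nonzero (pairs with < 3 such samples get 0).
#'   Default `FALSE`.
#' @return Symmetric matrix of correlations with unit diagonal.
#' @export
pairwise_correlation <- function(X, method = c("pearson", "spearman"),
                                 jointly_present = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 samples to correlate features")
  if (jointly_present) {
    Xm <- t(X)
    Xm[Xm == 0] <- NA
    R <- suppressWarnings(
      stats::cor(Xm, method = method, use = "pairwise.complete.obs"))
    npair <- crossprod(!is.na(Xm) * 1)
    R[npair < 3] <- 0
  } else {
    R <- suppressWarnings(stats::cor(t(X), method = method))
  }
  R[is.na(R)] <- 0   # zero-variance features: never connected
  diag(R) <- 1
  dimnames(R) <- list(rownames(X), rownames(X))
  R
}

#' Threshold the correlation network
#'
#' Edge between features i and j (i != j) iff `|corr_ij| > c` (strict).
#'
#' @param corr Symmetric correlation matrix.
#' @param c Threshold in (0, 1).
#' @return Logical adjacency matrix (no self-loops).
#' @export
threshold_graph <- function(corr, c = 0.95) {
  if (!(is.numeric(c) && length(c) == 1L && c > 0 && c < 1)) {
    stop("threshold c must lie in (0, 1)")
  }
  A <- abs(as.matrix(corr)) > c
  diag(A) <- FALSE
  A
}

#' Connected components of the feature network
#'
#' Features in the same connected component form one feature-set; isolated
#' features become singleton sets.  Sets are ordered by their smallest member
#' index and members are sorted within each set.
#'
#' @param adjacency Logical/0-1 symmetric adjacency matrix.
#' @return A `feature_partition`: list with `sets` (list of integer index
#'   vectors), `membership` (set id per feature), and `feature_ids`.
#' @export
connected_components <- function(adjacency) {
  A <- as.matrix(adjacency)
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sets <- split(seq_along(comp), comp)
  sets <- lapply(sets, sort)
  sets <- sets[order(vapply(sets, min, 1L))]
  names(sets) <- paste0("set", seq_along(sets))
  membership <- integer(length(comp))
  for (k in seq_along(sets)) membership[sets[[k]]] <- k
  structure(list(sets = sets, membership = membership,
                 feature_ids = rownames(A)),
            class = "feature_partition")
}

#' Group features into feature-sets by correlation network
#'
#' Convenience wrapper: correlation, thresholding and connected components in
#' one call.  The default threshold 0.95 targets near-duplicate features
#' (adducts/fragments of the same metabolite often correlate at 0.99).
#'
#' @inheritParams pairwise_correlation
#' @param threshold Correlation threshold in (0, 1), default 0.95.
#' @return A `feature_partition` with `threshold` and `method` recorded.
#' @export
#' @examples
#' X <- rbind(a = 1:5, b = (1:5) * 2 + 0.01, c = c(5, 3, 4, 1, 2))
#' group_features(X, threshold = 0.9)$sets
group_features <- function(X, threshold = 0.95,
                           method = c("pearson", "spearman"),
                           jointly_present = FALSE) {
  method <- match.arg(method)
  R <- pairwise_correlation(X, method = method,
                            jointly_present = jointly_present)
  part <- connected_components(threshold_graph(R, threshold))
  part$threshold <- threshold
  part$method <- method
  part
}

#' @export
print.feature_partition <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("Feature partition: %d features in %d sets (largest = %d)\n",
              sum(sizes), length(sizes), max(sizes)))
  if (!is.null(x$threshold)) {
    cat(sprintf("  |%s correlation| > %g\n", x$method, x$threshold))
  }
  invisible(x)
}
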