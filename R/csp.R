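#' Fit common spatial patterns for one band
#'
#' Solves the generalized eigenproblem `C1 w = lambda C2 w` on the
#' class-average covariance matrices, after shrinking each average toward a
#' scaled identity by `shrinkage` (Ledoit-Wolf-style target `tr(C)/d * I`;
#' small windows at the downsampled rate make the raw averages
#' ill-conditioned). Each eigenvector w maximizes the ratio of class-1 to
#' class-2 projected variance at its eigenvalue; all `d` filters are
#' retained, sorted by eigenvalue descending, with the sign convention that
#' each filter's largest-magnitude component is positive.
#'
#' @param cov_class1,cov_class2 per-trial covariance stacks
#'   (trials x d x d arrays, or `wb_cov` objects, or single d x d matrices
#'   already averaged).
#' @param shrinkage shrinkage intensity in \[0, 1\].
#' @return a `csp_model`: `W` (filters x channels matrix), `lambda`
#'   (descending generalized eigenvalues), `shrinkage`.
#' @export
fit_csp <- function(cov_class1, cov_class2, shrinkage = 0.1) {
  avg <- function(x) {
    if (inherits(x, "wb_cov")) x <- x$covs
    if (is.matrix(x)) return(x)
    if (length(dim(x)) == 3) {
      if (dim(x)[1] < 2) stopf("need at least 2 trials per class")
      return(apply(x, c(2, 3), mean))
    }
    stopf("covariance input must be a matrix or trials x d x d array")
  }
  C1 <- avg(cov_class1); C2 <- avg(cov_class2)
  if (!all(dim(C1) == dim(C2))) stopf("class covariances differ in dimension")
  d <- nrow(C1)
  shrink <- function(C) {
    C <- (C + t(C)) / 2
    if (shrinkage > 0)
      C <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / d) * diag(d)
    C
  }
  C1 <- shrink(C1); C2 <- shrink(C2)
  R <- tryCatch(chol(C2), error = function(e)
    stopf("class-2 covariance is singular; refit with nonzero shrinkage"))
  Rinv <- backsolve(R, diag(d))
  M <- t(Rinv) %*% C1 %*% Rinv
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)   # eigenvalues descending
  W <- Rinv %*% eg$vectors                        # columns = filters
  for (j in seq_len(d)) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = t(W), lambda = eg$values, shrinkage = shrinkage,
                 C1 = C1, C2 = C2),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters, lambda %.3g .. %.3g (shrinkage %.2g)\n",
              nrow(x$W), x$lambda[1], x$lambda[length(x$lambda)], x$shrinkage))
  invisible(x)
}

#' Variance features of spatially filtered signals
#'
#' For each trial and each CSP filter w, the variance of the filtered
#' band-limited signal equals the quadratic form `w' Sigma_trial w` on the
#' trial's band covariance, so features are computed directly from the
#' per-trial covariance stack.
#'
#' @param covs per-trial covariances for one band (trials x d x d array or a
#'   `wb_cov`).
#' @param model a [fit_csp()] model trained on the same channel set.
#' @return trials x filters matrix of nonnegative variance features with a
#'   `"meta"` attribute (filter index and eigenvalue).
#' @export
extract_variance_features <- function(covs, model) {
  if (inherits(covs, "wb_cov")) covs <- covs$covs
  d <- dim(covs)[2]
  if (ncol(model$W) != d)
    stopf("model has %d channels but data has %d", ncol(model$W), d)
  n <- dim(covs)[1]
  flat <- matrix(covs, nrow = n)                 # n x d^2 (column-major)
  Wouter <- apply(model$W, 1, function(w) as.numeric(tcrossprod(w)))
  feat <- flat %*% Wouter
  attr(feat, "meta") <- data.frame(filter = seq_len(nrow(model$W)),
                                   lambda = model$lambda)
  feat
}

#' Fisher-score feature selection
#'
#' Scores each feature by `(mu1 - mu2)^2 / (s1^2 + s2^2)` between the two
#' classes and returns the indices of the `k` largest scores (ties broken by
#' lower feature index). A zero score occurs iff the class means coincide.
#'
#' @param features trials x features matrix.
#' @param labels per-trial class labels (2 classes).
#' @param k number of features to keep.
#' @return list with `scores` (per feature) and `selected` (indices of the
#'   top `k`).
#' @export
fisher_select <- function(features, labels, k = 5) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("fisher_select needs exactly 2 classes")
  if (k > ncol(features)) stopf("k = %d exceeds %d features", k, ncol(features))
  idx1 <- labels == levels(labels)[1]
  if (sum(idx1) < 2 || sum(!idx1) < 2)
    stopf("each class needs at least 2 trials for a variance")
  m1 <- colMeans(features[idx1, , drop = FALSE])
  m2 <- colMeans(features[!idx1, , drop = FALSE])
  v1 <- apply(features[idx1, , drop = FALSE], 2, var)
  v2 <- apply(features[!idx1, , drop = FALSE], 2, var)
  num <- (m1 - m2)^2
  den <- v1 + v2
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  selected <- order(-scores, seq_along(scores))[seq_len(k)]
  list(scores = scores, selected = selected)
}

# Multi-class generalization used by the identity decoder: ratio of
# between-class to within-class variance.
fisher_scores_multiclass <- function(features, labels) {
  labels <- as.factor(labels)
  n <- nrow(features)
  grand <- colMeans(features)
  between <- 0; within <- 0
  for (lv in levels(labels)) {
    idx <- labels == lv
    m <- colMeans(features[idx, , drop = FALSE])
    v <- apply(features[idx, , drop = FALSE], 2, var)
    between <- between + sum(idx) * (m - grand)^2
    within <- within + sum(idx) * v
  }
  ifelse(within > 0, between / within,
         ifelse(between > 0, Inf, 0))
}
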