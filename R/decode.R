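#' Sliding-window grid
#'
#' All maximal windows of `length` ms fully inside `span`, stepped by `step`
#' ms; intervals are closed at both ends. The default analysis span
#' 0-2000 ms with 300-ms windows stepped 20 ms gives 86 windows with
#' midpoints 150, 170, ..., 1850 ms.
#'
#' @param span ms pair.
#' @param length window length in ms.
#' @param step step between window starts in ms.
#' @return a `window_grid`: data frame `windows` (`start`, `end`,
#'   `midpoint`) plus the grid parameters.
#' @export
build_window_grid <- function(span = c(0, 2000), length = 300, step = 20) {
  if (length > diff(span)) stopf("window length %g exceeds span width %g",
                                 length, diff(span))
  if (step <= 0) stopf("step must be positive")
  starts <- seq(span[1], span[2] - length, by = step)
  structure(list(windows = data.frame(start = starts, end = starts + length,
                                      midpoint = starts + length / 2),
                 span = span, length = length, step = step),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g ms stepped %g ms over [%g, %g] ms\n",
              nrow(x$windows), x$length, x$step, x$span[1], x$span[2]))
  invisible(x)
}

#' Stratified cross-validation folds
#'
#' Assigns trials to `k` folds, shuffling within class and dealing classes
#' round-robin with a running pointer so that overall fold sizes differ by
#' at most one and each class is spread as evenly as possible (class
#' imbalance is preserved in every fold).
#'
#' @param labels per-trial class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment in `1..k` per trial.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stopf("every class needs at least k = %d trials", k)
  folds <- integer(length(labels))
  with_seed(seed, {
    ptr <- 0L
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- ptr + length(idx)
    }
  })
  folds
}

#' Train a Gaussian naive-Bayes classifier
#'
#' Class-conditional independent Gaussians per feature with empirical class
#' priors. Class variances are floored at `1e-9` times the feature's pooled
#' variance (so degenerate, zero-variance features cannot produce division
#' errors).
#'
#' @param features trials x features matrix.
#' @param labels per-trial class labels (>= 2 classes, >= 2 trials each).
#' @return an `nb_model`.
#' @export
train_nb <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("naive Bayes needs at least 2 classes")
  if (any(table(labels) < 2)) stopf("every class needs at least 2 trials")
  classes <- levels(labels)
  p <- ncol(features)
  mu <- matrix(0, length(classes), p)
  va <- matrix(0, length(classes), p)
  for (ci in seq_along(classes)) {
    idx <- labels == classes[ci]
    mu[ci, ] <- colMeans(features[idx, , drop = FALSE])
    va[ci, ] <- apply(features[idx, , drop = FALSE], 2, var)
  }
  pooled <- apply(features, 2, var)
  vfloor <- pmax(1e-9 * pooled, 1e-12)
  va <- pmax(va, rep(vfloor, each = length(classes)))
  structure(list(classes = classes,
                 priors = as.numeric(table(labels)) / length(labels),
                 means = mu, vars = va),
            class = "nb_model")
}

#' Predict from a naive-Bayes model
#'
#' @param model an [train_nb()] model.
#' @param features trials x features matrix.
#' @param type `"class"` for labels, `"posterior"` for normalized class
#'   posteriors.
#' @return character vector of classes or a trials x classes posterior
#'   matrix.
#' @export
predict_nb <- function(model, features, type = c("class", "posterior")) {
  type <- match.arg(type)
  features <- as.matrix(features)
  n <- nrow(features)
  ll <- matrix(0, n, length(model$classes))
  for (ci in seq_along(model$classes)) {
    contrib <- vapply(seq_len(ncol(features)), function(j)
      -0.5 * log(2 * pi * model$vars[ci, j]) -
        (features[, j] - model$means[ci, j])^2 / (2 * model$vars[ci, j]),
      numeric(n))
    ll[, ci] <- log(model$priors[ci]) +
      rowSums(matrix(contrib, nrow = n))
  }
  if (type == "class")
    return(model$classes[max.col(ll, ties.method = "first")])
  post <- exp(ll - apply(ll, 1, max))
  post / rowSums(post)
}

# Pure-R reference for the compiled sweep: one full timecourse for a single
# binary label assignment, over precomputed window x band covariances.
decode_tc_r <- function(covs, n_windows, n_bands, y01, folds, n_select,
                        shrinkage, fit_scope = "fold") {
  n <- dim(covs)[1]; d2 <- dim(covs)[2]; d <- as.integer(sqrt(d2))
  k_folds <- max(folds)
  acc <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    window_features <- function(idx) {
      feat <- matrix(0, n, n_bands * d)
      for (b in seq_len(n_bands)) {
        X <- covs[, , (w - 1) * n_bands + b]
        C1 <- matrix(colMeans(X[idx & y01 == 0, , drop = FALSE]), d, d)
        C2 <- matrix(colMeans(X[idx & y01 == 1, , drop = FALSE]), d, d)
        mod <- fit_csp(C1, C2, shrinkage = shrinkage)
        Wouter <- apply(mod$W, 1, function(wv) as.numeric(tcrossprod(wv)))
        feat[, (b - 1) * d + seq_len(d)] <- X %*% Wouter
      }
      feat
    }
    if (fit_scope == "all") {
      feat_all <- window_features(rep(TRUE, n))
      sel_all <- fisher_select(feat_all, y01, k = n_select)$selected
    }
    fold_acc <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      train <- folds != f
      if (fit_scope == "all") {
        feat <- feat_all
        sel <- sel_all
      } else {
        feat <- window_features(train)
        sel <- fisher_select(feat[train, , drop = FALSE], y01[train],
                             k = n_select)$selected
      }
      nb <- train_nb(feat[train, sel, drop = FALSE], y01[train])
      pred <- predict_nb(nb, feat[folds == f, sel, drop = FALSE])
      truth <- as.character(y01[folds == f])
      fold_acc[f] <- mean(pred == truth)
    }
    acc[w] <- 100 * mean(fold_acc)
  }
  acc
}

# Resolve tfr-or-precomputed-covariances input.
as_wb_cov_set <- function(x, grid, bands = band_table()) {
  if (inherits(x, "wb_cov_set")) {
    if (!is.null(grid) && !identical(x$grid$windows, grid$windows))
      stopf("precomputed covariances were built on a different grid")
    return(x)
  }
  if (inherits(x, "tfr")) return(windowed_band_covs(x, grid, bands))
  stopf("expected a 'tfr' or 'wb_cov_set' object")
}

binary_y01 <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("binary decoding needs exactly 2 classes")
  as.integer(labels) - 1L
}

#' Cross-validated decoding accuracy in one window
#'
#' Runs the full leakage-safe stack on a single window: stratified k-fold
#' split, then per fold CSP fit on training trials only, variance-feature
#' extraction, Fisher selection of the top `n_select` features on training
#' trials only, Gaussian naive Bayes, scoring on the held-out fold. Returns
#' the mean test accuracy across folds in percent.
#'
#' @param x a [morlet_tfr()] result (or a precomputed
#'   [windowed_band_covs()] for a single-window grid).
#' @param labels per-trial binary labels.
#' @param window ms pair.
#' @param bands band table, default [band_table()].
#' @param k_folds number of folds.
#' @param seed seed for the fold assignment.
#' @param n_select number of Fisher-selected features.
#' @param shrinkage CSP covariance shrinkage.
#' @param engine `"cpp"` (compiled) or `"r"` (reference); both give the same
#'   result.
#' @param fit_scope `"fold"` (default, leakage-safe: CSP and Fisher
#'   selection are re-fit inside every training fold) or `"all"` (literal
#'   variant fitting them on all trials before cross-validating the
#'   classifier; implies the R engine).
#' @return accuracy in percent.
#' @export
crossval_accuracy <- function(x, labels, window, bands = band_table(),
                              k_folds = 5, seed = 1, n_select = 5,
                              shrinkage = 0.1, engine = c("cpp", "r"),
                              fit_scope = c("fold", "all")) {
  engine <- match.arg(engine)
  fit_scope <- match.arg(fit_scope)
  if (fit_scope == "all") engine <- "r"
  grid <- build_window_grid(span = window, length = diff(window), step = diff(window))
  wbc <- as_wb_cov_set(x, grid, bands)
  y01 <- binary_y01(labels)
  if (any(table(y01) < k_folds)) stopf("every class needs >= k_folds trials")
  folds <- make_folds(y01, k = k_folds, seed = seed)
  if (engine == "cpp")
    cpp_decode_timecourse(wbc$covs, 1L, length(wbc$bands), y01, folds - 1L,
                          as.integer(n_select), shrinkage)[1]
  else
    decode_tc_r(wbc$covs, 1L, length(wbc$bands), y01, folds, n_select,
                shrinkage, fit_scope)[1]
}

#' Time-resolved binary decoding
#'
#' Applies [crossval_accuracy()]'s stack to every window of the grid,
#' reusing a single seeded fold assignment across windows so that
#' between-window accuracy differences are attributable to time, not
#' resampling.
#'
#' @inheritParams crossval_accuracy
#' @param grid a [build_window_grid()].
#' @param descriptor optional list describing the analysis (subject, phase,
#'   condition, feature), attached to the result.
#' @return a `decoding_timecourse`: data frame with `midpoint_ms` and
#'   `accuracy_pct`.
#' @export
sliding_window_decode <- function(x, labels, grid = build_window_grid(),
                                  bands = band_table(), k_folds = 5,
                                  seed = 1, n_select = 5, shrinkage = 0.1,
                                  engine = c("cpp", "r"), descriptor = NULL,
                                  fit_scope = c("fold", "all")) {
  engine <- match.arg(engine)
  fit_scope <- match.arg(fit_scope)
  if (fit_scope == "all") engine <- "r"
  wbc <- as_wb_cov_set(x, grid, bands)
  y01 <- binary_y01(labels)
  if (any(table(y01) < k_folds)) stopf("every class needs >= k_folds trials")
  folds <- make_folds(y01, k = k_folds, seed = seed)
  n_w <- nrow(grid$windows)
  acc <- if (engine == "cpp")
    cpp_decode_timecourse(wbc$covs, n_w, length(wbc$bands), y01, folds - 1L,
                          as.integer(n_select), shrinkage)
  else decode_tc_r(wbc$covs, n_w, length(wbc$bands), y01, folds, n_select,
                   shrinkage, fit_scope)
  structure(data.frame(midpoint_ms = grid$windows$midpoint,
                       accuracy_pct = acc),
            grid = grid, descriptor = descriptor,
            class = c("decoding_timecourse", "data.frame"))
}

#' Time-resolved three-class context-identity decoding
#'
#' One-vs-rest CSP per class (the three per-class filter sets are pooled),
#' multi-class Fisher selection of the top `n_select` features, and a
#' three-class Gaussian naive Bayes, cross-validated exactly as the binary
#' decoder. Chance level is 33.3%.
#'
#' @inheritParams sliding_window_decode
#' @param labels per-trial identity labels (exactly 3 classes, each with at
#'   least `k_folds` trials).
#' @return a `decoding_timecourse`.
#' @export
multiclass_decode <- function(x, labels, grid = build_window_grid(),
                              bands = band_table(), k_folds = 5, seed = 1,
                              n_select = 5, shrinkage = 0.1,
                              descriptor = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 3) stopf("identity decoding expects exactly 3 classes")
  if (any(table(labels) < k_folds)) stopf("every class needs >= k_folds trials")
  wbc <- as_wb_cov_set(x, grid, bands)
  covs <- wbc$covs
  n <- dim(covs)[1]; d2 <- dim(covs)[2]; d <- as.integer(sqrt(d2))
  n_bands <- length(wbc$bands)
  folds <- make_folds(labels, k = k_folds, seed = seed)
  k_cls <- nlevels(labels)
  n_w <- nrow(grid$windows)
  acc <- numeric(n_w)
  for (w in seq_len(n_w)) {
    fold_acc <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      train <- folds != f
      feat <- matrix(0, n, n_bands * k_cls * d)
      for (b in seq_len(n_bands)) {
        X <- covs[, , (w - 1) * n_bands + b]
        for (ci in seq_len(k_cls)) {
          in_c <- labels == levels(labels)[ci]
          C1 <- matrix(colMeans(X[train & in_c, , drop = FALSE]), d, d)
          C2 <- matrix(colMeans(X[train & !in_c, , drop = FALSE]), d, d)
          mod <- fit_csp(C1, C2, shrinkage = shrinkage)
          Wouter <- apply(mod$W, 1, function(wv) as.numeric(tcrossprod(wv)))
          cols <- ((b - 1) * k_cls + (ci - 1)) * d + seq_len(d)
          feat[, cols] <- X %*% Wouter
        }
      }
      scores <- fisher_scores_multiclass(feat[train, , drop = FALSE],
                                         labels[train])
      sel <- order(-scores, seq_along(scores))[seq_len(min(n_select, length(scores)))]
      nb <- train_nb(feat[train, sel, drop = FALSE], labels[train])
      pred <- predict_nb(nb, feat[folds == f, sel, drop = FALSE])
      fold_acc[f] <- mean(pred == as.character(labels[folds == f]))
    }
    acc[w] <- 100 * mean(fold_acc)
  }
  structure(data.frame(midpoint_ms = grid$windows$midpoint,
                       accuracy_pct = acc),
            grid = grid, descriptor = descriptor,
            class = c("decoding_timecourse", "data.frame"))
}
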