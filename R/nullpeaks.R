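#' Permutation-based empirical chance distribution
#'
#' Repeats the full time-resolved cross-validated decoding with labels
#' randomly permuted (without replacement, preserving class counts) on each
#' repetition. Each repetition gets its own permutation-indexed seed for
#' both the shuffle and a fresh fold assignment, so any single permutation
#' is reproducible in isolation. From the permutations x windows accuracy
#' matrix the per-window 95th percentiles are computed, and the conservative
#' subject-level significance threshold is the highest per-window percentile
#' across windows.
#'
#' @inheritParams sliding_window_decode
#' @param n_perm number of label permutations (500 for a full analysis;
#'   scaled-down values are fine for calibration studies).
#' @param percentile per-window percentile defining the threshold.
#' @return a `null_distribution`: `accuracies` (n_perm x windows matrix, %),
#'   `per_window_p95`, `conservative_threshold`, `midpoint_ms`, `n_perm`.
#' @export
permutation_null <- function(x, labels, grid = build_window_grid(),
                             bands = band_table(), n_perm = 500,
                             k_folds = 5, seed = 1, n_select = 5,
                             shrinkage = 0.1, percentile = 0.95,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  wbc <- as_wb_cov_set(x, grid, bands)
  y01 <- binary_y01(labels)
  if (any(table(y01) < k_folds)) stopf("every class needs >= k_folds trials")
  n <- length(y01)
  n_w <- nrow(grid$windows)
  perm_labels <- matrix(0L, n_perm, n)
  perm_folds <- matrix(0L, n_perm, n)
  for (r in seq_len(n_perm)) {
    yp <- with_seed(derive_seed(seed, r, 1), y01[sample.int(n)])
    perm_labels[r, ] <- yp
    perm_folds[r, ] <- make_folds(yp, k = k_folds,
                                  seed = derive_seed(seed, r, 2))
  }
  accs <- if (engine == "cpp") {
    cpp_permutation_null(wbc$covs, n_w, length(wbc$bands), perm_labels,
                         perm_folds - 1L, as.integer(n_select), shrinkage)
  } else {
    t(sapply(seq_len(n_perm), function(r)
      decode_tc_r(wbc$covs, n_w, length(wbc$bands), perm_labels[r, ],
                  perm_folds[r, ], n_select, shrinkage)))
  }
  p95 <- apply(accs, 2, function(v)
    unname(stats::quantile(v, percentile, type = 7, names = FALSE)))
  structure(list(accuracies = accs, per_window_p95 = p95,
                 conservative_threshold = max(p95),
                 midpoint_ms = grid$windows$midpoint,
                 n_perm = n_perm, percentile = percentile),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations x %d windows; conservative threshold %.1f%%\n",
              x$n_perm, ncol(x$accuracies), x$conservative_threshold))
  invisible(x)
}

#' Earliest significant local peak of a decoding timecourse
#'
#' A window is a candidate peak when its accuracy is strictly greater than
#' every other window within the temporal neighborhood (midpoint distance
#' <= `neighborhood` ms; exact ties disqualify). Candidates at or below
#' `threshold` are discarded, and the earliest survivor is the peak moment.
#' Edge windows compete only against their existing neighbors.
#'
#' @param tc a `decoding_timecourse` (uniform midpoint grid).
#' @param threshold significance threshold in percent (typically the
#'   conservative threshold of a [permutation_null()]).
#' @param neighborhood half-width of the temporal neighborhood in ms; must
#'   be a multiple of the grid step.
#' @return a `peak_result`: `midpoint_ms` (NA if no candidate survives),
#'   `accuracy_pct`, `is_significant`, `candidates` (all local peaks with
#'   their accuracies).
#' @export
find_earliest_peak <- function(tc, threshold, neighborhood = 60) {
  if (nrow(tc) == 0) stopf("empty timecourse")
  mid <- tc$midpoint_ms
  acc <- tc$accuracy_pct
  if (nrow(tc) > 1) {
    steps <- diff(mid)
    if (max(abs(steps - steps[1])) > 1e-9) stopf("timecourse grid is not uniform")
    if (abs(neighborhood / steps[1] - round(neighborhood / steps[1])) > 1e-9)
      stopf("neighborhood must be a multiple of the grid step")
  }
  is_cand <- vapply(seq_along(mid), function(i) {
    nb <- which(abs(mid - mid[i]) <= neighborhood & seq_along(mid) != i)
    all(acc[i] > acc[nb])
  }, logical(1))
  candidates <- data.frame(midpoint_ms = mid[is_cand],
                           accuracy_pct = acc[is_cand])
  surviving <- candidates[candidates$accuracy_pct > threshold, , drop = FALSE]
  if (nrow(surviving) == 0) {
    res <- list(midpoint_ms = NA_real_, accuracy_pct = NA_real_,
                is_significant = FALSE, candidates = candidates,
                threshold = threshold)
  } else {
    res <- list(midpoint_ms = surviving$midpoint_ms[1],
                accuracy_pct = surviving$accuracy_pct[1],
                is_significant = TRUE, candidates = candidates,
                threshold = threshold)
  }
  structure(res, class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  if (x$is_significant)
    cat(sprintf("<peak_result> earliest significant peak at %g ms (%.1f%% > %.1f%%)\n",
                x$midpoint_ms, x$accuracy_pct, x$threshold))
  else
    cat(sprintf("<peak_result> no significant peak (threshold %.1f%%; %d candidates)\n",
                x$threshold, nrow(x$candidates)))
  invisible(x)
}

#' Actual-minus-chance decoding timecourse
#'
#' Subtracts the per-window empirical chance level (the null distribution's
#' column means) from an actual decoding timecourse. Note the two distinct
#' uses of the null: its per-window mean defines chance for these difference
#' timecourses, while the conservative max-percentile defines peak
#' significance.
#'
#' @param tc a `decoding_timecourse`.
#' @param null a [permutation_null()] on the same grid.
#' @return data frame with `midpoint_ms` and `difference_pct`.
#' @export
real_minus_chance <- function(tc, null) {
  if (length(null$midpoint_ms) != nrow(tc) ||
      max(abs(null$midpoint_ms - tc$midpoint_ms)) > 1e-9)
    stopf("timecourse and null distribution are on different grids")
  data.frame(midpoint_ms = tc$midpoint_ms,
             difference_pct = tc$accuracy_pct - colMeans(null$accuracies))
}

#' Group-level actual-minus-chance timecourse
#'
#' Cross-subject mean of per-subject difference timecourses with a
#' t-distribution 95% confidence interval per window; windows whose CI
#' excludes 0 are flagged as significantly above/below chance.
#'
#' @param differences list of [real_minus_chance()] outputs (or a subjects x
#'   windows matrix).
#' @param conf confidence level.
#' @return data frame with `midpoint_ms`, `mean_diff_pct`, `ci_halfwidth`,
#'   `significant`.
#' @export
group_difference_timecourse <- function(differences, conf = 0.95) {
  if (is.list(differences) && !is.data.frame(differences) &&
      !is.matrix(differences)) {
    mid <- differences[[1]]$midpoint_ms
    mat <- t(vapply(differences, function(d) d$difference_pct,
                    numeric(length(mid))))
  } else {
    mat <- as.matrix(differences)
    mid <- as.numeric(colnames(mat) %||% seq_len(ncol(mat)))
  }
  n <- nrow(mat)
  if (n < 2) stopf("group timecourse needs at least 2 subjects")
  m <- colMeans(mat)
  sem <- apply(mat, 2, sd) / sqrt(n)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sem
  data.frame(midpoint_ms = mid, mean_diff_pct = m, ci_halfwidth = half,
             significant = (m - half) > 0 | (m + half) < 0)
}
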