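#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over `interval`
#' (default -300 to -100 ms before stimulus onset, the re-baselining window
#' used after ocular-component removal).
#'
#' @param epochs an [epoch_set()].
#' @param interval ms pair, closed at both ends; must lie inside the epoch.
#' @return the baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, interval = c(-300, -100)) {
  t_ms <- epoch_times(epochs)
  if (interval[1] < t_ms[1] || interval[2] > t_ms[length(t_ms)])
    stopf("baseline interval [%g, %g] ms lies outside the epoch",
          interval[1], interval[2])
  idx <- which(t_ms >= interval[1] & t_ms <= interval[2])
  if (length(idx) == 0) stopf("baseline interval contains no samples")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(base, dim = dim(epochs$data))
  epochs
}

# Max of sliding-window ranges (max - min) per epoch x channel, for windows
# of win_ms stepped by step_ms with both edges inside [t_lo, t_hi].
windowed_range_stat <- function(data, t_ms, win_ms, step_ms,
                                t_lo = -Inf, t_hi = Inf, channels = NULL) {
  if (is.null(channels)) channels <- seq_len(dim(data)[2])
  t_lo <- max(t_lo, t_ms[1])
  t_hi <- min(t_hi, t_ms[length(t_ms)])
  starts <- seq(t_lo, t_hi - win_ms, by = step_ms)
  starts <- starts[starts + win_ms <= t_hi]
  if (length(starts) == 0) stopf("no complete windows fit the interval")
  n_ep <- dim(data)[1]
  stat <- numeric(n_ep)
  for (s in starts) {
    idx <- which(t_ms >= s & t_ms <= s + win_ms)
    sub <- data[, channels, idx, drop = FALSE]
    rng <- apply(sub, c(1, 2), function(v) max(v) - min(v))
    stat <- pmax(stat, apply(matrix(rng, nrow = n_ep), 1, max))
  }
  stat
}

#' Automated epoch rejection
#'
#' Applies the three data-driven rejection rules and removes the union of
#' flagged epochs:
#' \enumerate{
#'   \item voltage range within a 400-ms window (stepped 100 ms across the
#'     epoch) greater than the 99th percentile of all epochs' values;
#'   \item linear-trend |slope| above the 95th percentile of all epochs'
#'     values, provided the linear fit reaches R-squared >= 0.30;
#'   \item voltage range within a 100-ms window (stepped 25 ms) between -150
#'     and +150 ms around stimulus onset greater than the 95th percentile,
#'     for frontal and eye electrodes only.
#' }
#' Each rule reduces an epoch to a single statistic (the max over its
#' channels and windows); percentiles are taken across epochs with linear
#' interpolation between order statistics, and comparisons are strict, so
#' identical epochs are never rejected.
#'
#' @param epochs an [epoch_set()] with at least 2 epochs.
#' @param frontal_channels channel names used by rule 3 (besides any channel
#'   with role `"eog"`).
#' @param r2_min minimum linear-fit R-squared for rule 2.
#' @return list with `epochs` (survivors, original order preserved) and
#'   `report` (a `rejection_report`: per-rule indices, combined indices,
#'   fraction rejected, thresholds).
#' @export
reject_epochs <- function(epochs,
                          frontal_channels = c("FP1", "FP2", "AF3", "AF4",
                                               "F7", "F8"),
                          r2_min = 0.30) {
  n_ep <- n_trials(epochs)
  if (n_ep < 2) stopf("rejection thresholds need at least 2 epochs")
  t_ms <- epoch_times(epochs)

  # Rule 1: 400-ms windows stepped 100 ms across the whole epoch.
  s1 <- windowed_range_stat(epochs$data, t_ms, 400, 100)
  thr1 <- percentile(s1, 0.99)
  r1 <- which(s1 > thr1)

  # Rule 2: per-channel linear trend over the whole epoch.
  n_ch <- n_channels(epochs)
  tt <- t_ms - mean(t_ms)
  sxx <- sum(tt^2)
  slope_stat <- numeric(n_ep)
  r2_stat <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    y <- matrix(epochs$data[e, , ], nrow = n_ch)       # channels x samples
    yc <- y - rowMeans(y)
    slopes <- as.numeric(yc %*% tt) / sxx
    ssr <- slopes^2 * sxx
    sst <- rowSums(yc^2)
    r2 <- ifelse(sst > 0, ssr / sst, 0)
    k <- which.max(abs(slopes))
    slope_stat[e] <- abs(slopes[k])
    r2_stat[e] <- r2[k]
  }
  thr2 <- percentile(slope_stat, 0.95)
  r2idx <- which(slope_stat > thr2 & r2_stat >= r2_min)

  # Rule 3: 100-ms windows stepped 25 ms, -150..150 ms, frontal/eye only.
  ch3 <- which(epochs$channel_names %in% frontal_channels |
                 epochs$channel_roles == "eog")
  if (length(ch3) > 0) {
    s3 <- windowed_range_stat(epochs$data, t_ms, 100, 25,
                              t_lo = -150, t_hi = 150, channels = ch3)
    thr3 <- percentile(s3, 0.95)
    r3 <- which(s3 > thr3)
  } else {
    thr3 <- NA_real_
    r3 <- integer(0)
  }

  rejected <- sort(unique(c(r1, r2idx, r3)))
  report <- structure(
    list(rule1 = r1, rule2 = r2idx, rule3 = r3, rejected = rejected,
         fraction_rejected = length(rejected) / n_ep,
         thresholds = c(rule1 = thr1, rule2 = thr2, rule3 = thr3)),
    class = "rejection_report")
  keep <- setdiff(seq_len(n_ep), rejected)
  list(epochs = subset_trials(epochs, keep), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d rejected (%.1f%%): rule1=%d rule2=%d rule3=%d\n",
              length(x$rejected), 100 * x$fraction_rejected,
              length(x$rule1), length(x$rule2), length(x$rule3)))
  invisible(x)
}

# Approximate scalp adjacency for the 32-electrode montage.
default_neighbors <- function() {
  list(
    FP1 = c("AF3", "F7", "F3"),        FP2 = c("AF4", "F8", "F4"),
    AF3 = c("FP1", "F3", "Fz", "F7"),  AF4 = c("FP2", "F4", "Fz", "F8"),
    F7  = c("FP1", "AF3", "F3", "FC5", "T7"),
    F3  = c("AF3", "F7", "Fz", "FC5", "FC1"),
    Fz  = c("AF3", "AF4", "F3", "F4", "FC1", "FC2"),
    F4  = c("AF4", "F8", "Fz", "FC6", "FC2"),
    F8  = c("FP2", "AF4", "F4", "FC6", "T8"),
    FC5 = c("F7", "F3", "C3", "T7", "FC1"),
    FC1 = c("F3", "Fz", "C3", "Cz", "FC5", "FC2"),
    FC2 = c("F4", "Fz", "C4", "Cz", "FC6", "FC1"),
    FC6 = c("F8", "F4", "C4", "T8", "FC2"),
    T7  = c("F7", "FC5", "C3", "CP5", "P7"),
    C3  = c("FC5", "FC1", "Cz", "CP5", "CP1", "T7"),
    Cz  = c("FC1", "FC2", "C3", "C4", "CP1", "CP2"),
    C4  = c("FC6", "FC2", "Cz", "CP6", "CP2", "T8"),
    T8  = c("F8", "FC6", "C4", "CP6", "P8"),
    CP5 = c("T7", "C3", "CP1", "P7", "P3"),
    CP1 = c("C3", "Cz", "CP5", "CP2", "P3", "Pz"),
    CP2 = c("C4", "Cz", "CP6", "CP1", "P4", "Pz"),
    CP6 = c("T8", "C4", "CP2", "P8", "P4"),
    P7  = c("T7", "CP5", "P3", "PO3", "O1"),
    P3  = c("CP5", "CP1", "Pz", "P7", "PO3"),
    Pz  = c("CP1", "CP2", "P3", "P4", "PO3", "PO4"),
    P4  = c("CP6", "CP2", "Pz", "P8", "PO4"),
    P8  = c("T8", "CP6", "P4", "PO4", "O2"),
    PO3 = c("P7", "P3", "Pz", "O1", "Oz"),
    PO4 = c("P8", "P4", "Pz", "O2", "Oz"),
    O1  = c("P7", "PO3", "Oz"),
    Oz  = c("O1", "O2", "PO3", "PO4"),
    O2  = c("P8", "PO4", "Oz"))
}

#' Interpolate a bad channel from its neighbors
#'
#' Replaces `channel` with the sample-wise arithmetic mean of its configured
#' neighbors (restricted to neighbors present in the data); all other
#' channels are untouched.
#'
#' @param epochs an [epoch_set()].
#' @param channel channel name to replace.
#' @param neighbors named list mapping channel name to neighbor names;
#'   defaults to an adjacency map for the 32-electrode montage.
#' @return the `epoch_set` with the channel interpolated.
#' @export
interpolate_channel <- function(epochs, channel, neighbors = default_neighbors()) {
  ci <- match(channel, epochs$channel_names)
  if (is.na(ci)) stopf("channel '%s' not present", channel)
  nb <- intersect(neighbors[[channel]], epochs$channel_names)
  if (length(nb) == 0) stopf("channel '%s' has no configured neighbors", channel)
  ni <- match(nb, epochs$channel_names)
  epochs$data[, ci, ] <- apply(epochs$data[, ni, , drop = FALSE], c(1, 3), mean)
  epochs
}
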