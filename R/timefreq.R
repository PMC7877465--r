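#' Oscillatory band definitions
#'
#' The five conventional bands used throughout: delta 3-4, theta 4-7,
#' alpha 8-14, beta 14-30, gamma 30-80 Hz.
#'
#' @return data frame with columns `name`, `lo`, `hi`.
#' @export
band_table <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(3, 4, 8, 14, 30),
             hi = c(4, 7, 14, 30, 80),
             stringsAsFactors = FALSE)
}

#' Frequency-bin membership per band
#'
#' Assigns each frequency bin to at most one band: bins are claimed from the
#' lowest band upward, and a bin sitting exactly on a shared boundary (e.g.
#' 4 Hz between delta and theta) belongs to the lower band only, so no bin
#' is counted twice.
#'
#' @param freqs frequency grid in Hz.
#' @param bands band definition table, default [band_table()].
#' @return named list of integer bin indices per band.
#' @export
band_bins <- function(freqs, bands = band_table()) {
  claimed <- logical(length(freqs))
  out <- list()
  for (i in seq_len(nrow(bands))) {
    idx <- which(freqs >= bands$lo[i] & freqs <= bands$hi[i] & !claimed)
    claimed[idx] <- TRUE
    out[[bands$name[i]]] <- idx
  }
  out
}

# Complex Morlet kernel at frequency f (Hz): Gaussian envelope with
# sigma_t = cycles / (2 pi f), unit energy, truncated at +/- 3.5 sigma_t.
morlet_kernel <- function(f, fs, cycles = 5) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  a <- (sigma_t * sqrt(pi))^(-0.5)
  a * exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with 5-cycle complex Morlet wavelets on
#' a grid of 78 linearly spaced frequencies from 3 to 80 Hz, then crops the
#' result to the analysis interval (0-2000 ms by default) and decimates to a
#' nominal 50.25-Hz grid. Because 50.25 Hz is not an integer divisor of
#' 256 Hz, decimation keeps every `round(fs / 50.25)`-th sample (every 5th at
#' 256 Hz, an effective 51.2 Hz); all downstream window arithmetic uses the
#' true millisecond labels of the kept samples, never sample counts. The
#' epoch must extend beyond the crop interval by at least half the longest
#' wavelet so edge-distorted samples are discarded.
#'
#' @param epochs an [epoch_set()].
#' @param freqs frequency grid (Hz).
#' @param cycles wavelet width in cycles.
#' @param crop analysis interval in ms.
#' @param target_rate nominal downsampled rate (Hz).
#' @return a `tfr` object: complex `coefficients`
#'   (trials x channels x frequencies x timepoints), `frequencies`,
#'   `times_ms`, `cycles`, `channel_names`, `trial_labels`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(3, 80, length.out = 78),
                       cycles = 5, crop = c(0, 2000), target_rate = 50.25) {
  fs <- epochs$sampling_rate
  t_ms <- epoch_times(epochs)
  sigma_lo <- cycles / (2 * pi * min(freqs))
  margin_needed <- 3.5 * sigma_lo * 1000 / 2   # half the longest kernel, ms
  if (t_ms[1] > crop[1] - margin_needed ||
      t_ms[length(t_ms)] < crop[2] + margin_needed)
    stopf("epoch too short: need %.0f ms margin beyond [%g, %g] ms for the longest wavelet",
          margin_needed, crop[1], crop[2])

  kernels <- lapply(freqs, morlet_kernel, fs = fs, cycles = cycles)
  n <- n_samples(epochs)
  decim <- max(1L, round(fs / target_rate))
  first <- which(t_ms >= crop[1])[1]
  keep <- seq.int(first, n, by = decim)
  keep <- keep[t_ms[keep] <= crop[2]]
  times_ms <- t_ms[keep]
  coef <- cpp_morlet_conv(epochs$data, dim(epochs$data), kernels,
                          as.integer(keep), fs)
  structure(list(coefficients = coef, frequencies = freqs,
                 times_ms = times_ms, cycles = cycles,
                 sampling_rate = fs / decim,
                 channel_names = epochs$channel_names,
                 trial_labels = epochs$trial_labels),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("<tfr> %d trials x %d channels x %d freqs (%g-%g Hz) x %d timepoints (%g-%g ms)\n",
              d[1], d[2], d[3], min(x$frequencies), max(x$frequencies), d[4],
              min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Per-trial band-limited windowed channel covariance
#'
#' For one frequency band and one time window, computes each trial's
#' channel-by-channel covariance as the real part of the wavelet
#' cross-spectral matrix averaged over the band's frequency bins and the
#' window's timepoints. The matrices are symmetric positive semi-definite by
#' construction and are the `C` inputs of the CSP eigenproblem.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param band band name or a row of [band_table()].
#' @param window ms pair, closed at both ends.
#' @return a `wb_cov` object: `covs` (trials x channels x channels array),
#'   `band`, `window`, `midpoint`.
#' @export
band_windowed_covariance <- function(tfr, band, window) {
  if (is.character(band)) {
    bt <- band_table()
    if (!band %in% bt$name) stopf("unknown band '%s'", band)
    band <- bt[bt$name == band, ]
  }
  bins <- band_bins(tfr$frequencies)[[band$name]]
  if (length(bins) == 0) stopf("band '%s' contains no frequency bins", band$name)
  tps <- which(tfr$times_ms >= window[1] & tfr$times_ms <= window[2])
  if (length(tps) == 0) stopf("window [%g, %g] ms contains no timepoints",
                              window[1], window[2])
  d <- dim(tfr$coefficients)[2]
  n <- dim(tfr$coefficients)[1]
  covs <- array(0, dim = c(n, d, d))
  m <- length(bins) * length(tps)
  for (tr in seq_len(n)) {
    x <- matrix(tfr$coefficients[tr, , bins, tps], nrow = d)  # d x (bins*tps)
    covs[tr, , ] <- (tcrossprod(Re(x)) + tcrossprod(Im(x))) / m
  }
  structure(list(covs = covs, band = band$name, window = window,
                 midpoint = mean(window)),
            class = "wb_cov")
}

#' Precompute per-trial covariances for every window x band cell
#'
#' Computes [band_windowed_covariance()] for every (window, band) pair of a
#' sliding-window grid in one pass (compiled), returning the flattened
#' matrices that the decoding sweep and the permutation null reuse across
#' label assignments.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param grid a [build_window_grid()].
#' @param bands band table, default [band_table()].
#' @return a `wb_cov_set`: `covs` (trials x d^2 x (windows*bands) array,
#'   slice order window-major), `grid`, `bands`, `n_channels`.
#' @export
windowed_band_covs <- function(tfr, grid, bands = band_table()) {
  bins <- band_bins(tfr$frequencies, bands)
  if (any(vapply(bins, length, 1L) == 0)) stopf("a band contains no frequency bins")
  tps <- lapply(seq_len(nrow(grid$windows)), function(i)
    which(tfr$times_ms >= grid$windows$start[i] &
            tfr$times_ms <= grid$windows$end[i]))
  if (any(vapply(tps, length, 1L) == 0)) stopf("a window contains no timepoints")
  covs <- cpp_window_band_covs(tfr$coefficients, dim(tfr$coefficients),
                               bins, tps)
  structure(list(covs = covs, grid = grid, bands = bands$name,
                 n_channels = dim(tfr$coefficients)[2],
                 labels_hint = tfr$trial_labels),
            class = "wb_cov_set")
}
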