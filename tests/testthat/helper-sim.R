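# Small shared fixtures, generated in code. The tiny spec keeps unit tests
# fast; acceptance-scale cohorts are built inside test-acceptance.R.

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 4, channel_names = c("O1", "O2", "Pz", "Cz"),
         n_trials_per_class = c(correct = 15, incorrect = 10),
         effect_band = "alpha", effect_window = c(400, 700),
         effect_size = 3, seed = 42),
    list(...))
  do.call(simulation_spec, args)
}

# Independent band-power oracle: mean periodogram power of each trial's
# window segment over the FFT bins inside [lo, hi] Hz, channel-weighted.
oracle_band_power <- function(epochs, lo, hi, window, weights = NULL) {
  t_ms <- epoch_times(epochs)
  idx <- which(t_ms >= window[1] & t_ms <= window[2])
  fs <- epochs$sampling_rate
  nfft <- length(idx)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  bins <- which(freqs >= lo & freqs <= hi & freqs <= fs / 2)
  d <- dim(epochs$data)[2]
  if (is.null(weights)) weights <- rep(1, d)
  vapply(seq_len(dim(epochs$data)[1]), function(tr) {
    pw <- vapply(seq_len(d), function(ch) {
      seg <- epochs$data[tr, ch, idx]
      sp <- Mod(stats::fft(seg))^2 / nfft
      sum(sp[bins])
    }, numeric(1))
    sum(weights * pw) / sum(weights)
  }, numeric(1))
}

# One cached small tfr + covariance set shared by decoding tests.
local_cache <- new.env()

cached_decodable <- function() {
  if (is.null(local_cache$dec)) {
    spec <- tiny_spec(n_trials_per_class = c(correct = 30, incorrect = 30),
                      effect_band = "beta", effect_size = 6,
                      effect_window = c(400, 700), seed = 7)
    ep <- generate_subject_epochs(spec)
    grid <- build_window_grid(c(0, 1100))
    tfr <- morlet_tfr(ep)
    local_cache$dec <- list(
      spec = spec, epochs = ep, grid = grid, tfr = tfr,
      wbc = windowed_band_covs(tfr, grid),
      labels = ep$trial_labels$outcome)
  }
  local_cache$dec
}
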