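#' Specification of a synthetic EEG subject
#'
#' Describes one simulated subject-condition recording: 32-channel, 256-Hz
#' epochs from -1000 to +3000 ms around stimulus onset, a 1/f^chi + white
#' broadband background, and a class-discriminative band-limited oscillation
#' confined to a latency window. The only systematic difference between the
#' "correct" and "incorrect" classes is the power of that oscillation: the
#' correct/incorrect band-power ratio is controlled by `effect_size`
#' (>= 1 means the correct class carries more power).
#'
#' Defaults mirror the recording this pipeline targets: 32 electrodes of the
#' extended 10-20 montage at 256 Hz, 190 trials split 60/40
#' correct/incorrect, and an alpha-band effect at 400-700 ms, the latency
#' range where context-feature decoding peaks.
#'
#' @param n_channels number of EEG channels.
#' @param channel_names channel labels; defaults to the 32-electrode montage
#'   (or its first `n_channels` entries).
#' @param sampling_rate sampling rate in Hz; must exceed 160 Hz so the gamma
#'   band (up to 80 Hz) is below Nyquist.
#' @param epoch_window epoch extent in ms relative to stimulus onset.
#' @param n_trials_per_class named counts `c(correct = , incorrect = )`;
#'   may be unequal.
#' @param effect_band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @param effect_window ms pair inside \[0, 2000\] where the discriminative
#'   power lives.
#' @param effect_size multiplicative band-power ratio correct/incorrect.
#' @param effect_amplitude median oscillation amplitude (uV) of the
#'   incorrect class; the correct class gets
#'   `effect_amplitude * sqrt(effect_size)`.
#' @param amplitude_sd_log trial-to-trial lognormal variability of the
#'   oscillation amplitude (SD on the log scale). Band power fluctuates
#'   strongly across trials in real recordings; without this the two classes
#'   would be almost deterministically separable. The multiplier is shared
#'   by both classes, so the class power ratio stays `effect_size` in
#'   expectation.
#' @param spatial_profile per-channel weights of the effect; default 1 on
#'   posterior channels (names containing O/P) and 0.3 elsewhere.
#' @param noise_model list with `exponent` (1/f^chi amplitude slope of the
#'   background), `pink_sd` and `white_sd` (uV), and `band` (Hz pair the
#'   background is confined to, mirroring the 0.5-125 Hz acquisition
#'   band-pass).
#' @param subject_sd_latency between-subject SD (ms) of the effect-window
#'   onset used by [generate_cohort()].
#' @param age subject age in years (metadata only).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_channels = 32,
                            channel_names = NULL,
                            sampling_rate = 256,
                            epoch_window = c(-1000, 3000),
                            n_trials_per_class = c(correct = 114, incorrect = 76),
                            effect_band = "alpha",
                            effect_window = c(400, 700),
                            effect_size = 1.5,
                            effect_amplitude = 15,
                            amplitude_sd_log = 0.3,
                            spatial_profile = NULL,
                            noise_model = list(exponent = 1, pink_sd = 10,
                                               white_sd = 2, band = c(0.5, 125)),
                            subject_sd_latency = 40,
                            age = 45,
                            seed = 1) {
  if (is.null(channel_names)) {
    if (n_channels > length(montage32))
      channel_names <- c(montage32, paste0("EX", seq_len(n_channels - 32)))[seq_len(n_channels)]
    else channel_names <- montage32[seq_len(n_channels)]
  }
  if (length(channel_names) != n_channels) stopf("need %d channel names", n_channels)
  if (!effect_band %in% band_table()$name)
    stopf("unknown band '%s' (use delta/theta/alpha/beta/gamma)", effect_band)
  if (sampling_rate <= 2 * 80)
    stopf("sampling_rate must exceed 160 Hz (Nyquist above the gamma band)")
  if (any(n_trials_per_class <= 0)) stopf("trial counts must be positive")
  if (effect_window[1] < 0 || effect_window[2] > 2000 ||
      effect_window[1] >= effect_window[2])
    stopf("effect_window must be an increasing pair inside [0, 2000] ms")
  if (effect_window[1] < epoch_window[1] || effect_window[2] > epoch_window[2])
    stopf("effect_window lies outside the epoch")
  if (effect_size <= 0) stopf("effect_size must be positive")
  if (is.null(spatial_profile))
    spatial_profile <- ifelse(grepl("O|P", channel_names), 1, 0.3)
  if (length(spatial_profile) != n_channels)
    stopf("spatial_profile must have one weight per channel")
  nm <- utils::modifyList(list(exponent = 1, pink_sd = 10, white_sd = 2,
                               band = c(0.5, 125)), as.list(noise_model))
  structure(list(n_channels = n_channels, channel_names = channel_names,
                 sampling_rate = sampling_rate, epoch_window = epoch_window,
                 n_trials_per_class = n_trials_per_class,
                 effect_band = effect_band, effect_window = effect_window,
                 effect_size = effect_size, effect_amplitude = effect_amplitude,
                 amplitude_sd_log = amplitude_sd_log,
                 spatial_profile = spatial_profile, noise_model = nm,
                 subject_sd_latency = subject_sd_latency, age = age,
                 seed = seed),
            class = "simulation_spec")
}

# Band-limited random background: random-phase spectral synthesis with
# amplitude ~ f^-chi inside `band`, plus a flat ("white") component in the
# same band, scaled to the requested standard deviations. Returns an
# n x n_cols matrix of independent realizations.
band_limited_noise <- function(n, fs, exponent, pink_sd, white_sd, band,
                               n_cols = 1) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:(floor(n / 2))          # positive, non-DC, non-Nyquist bins
  keep <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  nk <- length(keep)
  mk <- function(amp) {
    phases <- matrix(runif(nk * n_cols, 0, 2 * pi), nk, n_cols)
    z <- matrix(complex(real = 0), n, n_cols)
    z[keep, ] <- amp * exp(1i * phases)
    z[n + 2 - keep, ] <- Conj(z[keep, ])
    x <- Re(stats::mvfft(z, inverse = TRUE)) / n
    s <- apply(x, 2, stats::sd)
    sweep(x, 2, ifelse(s > 0, s, 1), "/")
  }
  pink <- mk(freqs[keep]^(-exponent))
  white <- mk(rep(1, nk))
  pink_sd * pink + white_sd * white
}

# Cosine (Hann) envelope over [w1, w2] ms on time grid t: smoothly tapered
# and peaked at the window center, so decodability has a genuine apex at
# the center of the effect window rather than a flat plateau.
effect_envelope <- function(t, w1, w2) {
  env <- numeric(length(t))
  inside <- t >= w1 & t <= w2
  u <- (t[inside] - w1) / (w2 - w1)  # 0..1
  env[inside] <- 0.5 * (1 - cos(2 * pi * u))
  env
}

#' Generate one subject's epoched EEG
#'
#' Draws `n_trials_per_class` epochs per outcome class. Every epoch is
#' independent broadband background noise on each channel; on top of it a
#' band-limited oscillation (carrier drawn uniformly inside `effect_band`,
#' random phase per trial) is added inside `effect_window`, weighted across
#' channels by `spatial_profile`. The incorrect class receives amplitude
#' `effect_amplitude`, the correct class `effect_amplitude * sqrt(effect_size)`,
#' so the injected band-power ratio equals `effect_size`. Trial order is
#' shuffled. The realized effect parameters are stored in the
#' `"ground_truth"` attribute.
#'
#' @param spec a [simulation_spec()].
#' @param phase,attended_feature,context_feature metadata copied into the
#'   trial labels.
#' @param subject_id subject identifier.
#' @return an [epoch_set()] with a `ground_truth` attribute.
#' @export
generate_subject_epochs <- function(spec, phase = "encoding",
                                    attended_feature = "color",
                                    context_feature = "color",
                                    subject_id = "s01") {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    n_samp <- round(diff(spec$epoch_window) / 1000 * fs)
    t_ms <- spec$epoch_window[1] + (seq_len(n_samp) - 1) / fs * 1000
    band <- band_table()
    b <- band[band$name == spec$effect_band, ]
    n_cor <- spec$n_trials_per_class[["correct"]]
    n_inc <- spec$n_trials_per_class[["incorrect"]]
    n_tot <- n_cor + n_inc
    outcome <- c(rep("correct", n_cor), rep("incorrect", n_inc))
    amp <- ifelse(outcome == "correct",
                  spec$effect_amplitude * sqrt(spec$effect_size),
                  spec$effect_amplitude)
    env <- effect_envelope(t_ms, spec$effect_window[1], spec$effect_window[2])
    data <- array(0, dim = c(n_tot, spec$n_channels, n_samp))
    nm <- spec$noise_model
    width <- b$hi - b$lo
    for (tr in seq_len(n_tot)) {
      f_carrier <- runif(1, b$lo + 0.1 * width, b$hi - 0.1 * width)
      phi <- runif(1, 0, 2 * pi)
      a_tr <- amp[tr] * exp(rnorm(1, 0, spec$amplitude_sd_log))
      osc <- a_tr * env * cos(2 * pi * f_carrier * (t_ms / 1000) + phi)
      bg <- band_limited_noise(n_samp, fs, nm$exponent, nm$pink_sd,
                               nm$white_sd, nm$band, spec$n_channels)
      data[tr, , ] <- t(bg + outer(osc, spec$spatial_profile))
    }
    ord <- sample.int(n_tot)
    data <- data[ord, , , drop = FALSE]
    labels <- data.frame(phase = phase, attended_feature = attended_feature,
                         context_feature = context_feature,
                         outcome = outcome[ord],
                         context_identity = NA_character_,
                         subject_id = subject_id, age = spec$age,
                         stringsAsFactors = FALSE)
    out <- epoch_set(data, fs, spec$epoch_window[1], spec$channel_names,
                     trial_labels = labels)
    attr(out, "ground_truth") <- data.frame(
      subject_id = subject_id, phase = phase,
      attended_feature = attended_feature, context_feature = context_feature,
      band = spec$effect_band, band_lo = b$lo, band_hi = b$hi,
      window_start = spec$effect_window[1], window_end = spec$effect_window[2],
      effect_size = spec$effect_size, amplitude = spec$effect_amplitude,
      stringsAsFactors = FALSE)
    out
  })
}

#' Generate epochs whose classes differ by context identity
#'
#' Variant of [generate_subject_epochs()] for the three-class
#' context-identity analysis: each identity class gets its own spatial
#' profile for the injected oscillation, so the classes are separable by
#' spatial pattern rather than overall power.
#'
#' @param spec a [simulation_spec()]; `effect_size` is ignored (all classes
#'   get amplitude `effect_amplitude`).
#' @param identities class names.
#' @param n_per_identity trials per identity.
#' @param profiles list of per-channel weight vectors, one per identity;
#'   default: disjoint channel blocks.
#' @inheritParams generate_subject_epochs
#' @return an [epoch_set()] with `context_identity` labels.
#' @export
generate_identity_epochs <- function(spec, identities = c("A", "B", "C"),
                                     n_per_identity = 40, profiles = NULL,
                                     phase = "encoding",
                                     attended_feature = "color",
                                     context_feature = "color",
                                     subject_id = "s01") {
  stopifnot(inherits(spec, "simulation_spec"))
  k <- length(identities)
  if (is.null(profiles)) {
    profiles <- lapply(seq_len(k), function(i) {
      w <- rep(0.05, spec$n_channels)
      idx <- seq.int(i, spec$n_channels, by = k)
      w[idx] <- 1
      w
    })
  }
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    n_samp <- round(diff(spec$epoch_window) / 1000 * fs)
    t_ms <- spec$epoch_window[1] + (seq_len(n_samp) - 1) / fs * 1000
    b <- band_table()[band_table()$name == spec$effect_band, ]
    n_tot <- k * n_per_identity
    id <- rep(identities, each = n_per_identity)
    env <- effect_envelope(t_ms, spec$effect_window[1], spec$effect_window[2])
    nm <- spec$noise_model
    width <- b$hi - b$lo
    data <- array(0, dim = c(n_tot, spec$n_channels, n_samp))
    for (tr in seq_len(n_tot)) {
      f_carrier <- runif(1, b$lo + 0.1 * width, b$hi - 0.1 * width)
      phi <- runif(1, 0, 2 * pi)
      a_tr <- spec$effect_amplitude * exp(rnorm(1, 0, spec$amplitude_sd_log))
      osc <- a_tr * env * cos(2 * pi * f_carrier * (t_ms / 1000) + phi)
      w <- profiles[[match(id[tr], identities)]]
      bg <- band_limited_noise(n_samp, fs, nm$exponent, nm$pink_sd,
                               nm$white_sd, nm$band, spec$n_channels)
      data[tr, , ] <- t(bg + outer(osc, w))
    }
    ord <- sample.int(n_tot)
    data <- data[ord, , , drop = FALSE]
    labels <- data.frame(phase = phase, attended_feature = attended_feature,
                         context_feature = context_feature,
                         outcome = "correct", context_identity = id[ord],
                         subject_id = subject_id, age = spec$age,
                         stringsAsFactors = FALSE)
    epoch_set(data, fs, spec$epoch_window[1], spec$channel_names,
              trial_labels = labels)
  })
}

#' Generate a cohort of synthetic subjects across condition cells
#'
#' Each subject gets one independent [epoch_set()] per condition cell
#' (phase x attended feature x context feature). The cell's ground-truth
#' effect window is the base spec's window shifted by that cell's entry in
#' `per_condition_latency_offsets`, plus independent Gaussian jitter with SD
#' `subject_sd_latency` per subject and cell. Ages are drawn uniformly over
#' `age_range`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param base_spec a [simulation_spec()] shared by all cells.
#' @param per_condition_latency_offsets data frame with columns `phase`,
#'   `attended_feature`, `context_feature`, `offset_ms`.
#' @param age_range ages are drawn uniformly over this range (years).
#' @param seed integer seed.
#' @return list with elements `subjects` (list of per-subject records:
#'   `subject_id`, `age`, `epochs` — a named list keyed
#'   `phase.attended.feature` — and `ground_truth`) and `ground_truth`
#'   (cohort-level table including the pre-jitter offsets).
#' @export
generate_cohort <- function(n_subjects, base_spec,
                            per_condition_latency_offsets,
                            age_range = c(18, 74), seed = 1) {
  if (n_subjects < 2) stopf("need at least 2 subjects for group statistics")
  off <- per_condition_latency_offsets
  req <- c("phase", "attended_feature", "context_feature", "offset_ms")
  if (!all(req %in% names(off)))
    stopf("offsets need columns %s", paste(req, collapse = ", "))
  ages <- with_seed(derive_seed(seed, 0),
                    runif(n_subjects, age_range[1], age_range[2]))
  subjects <- vector("list", n_subjects)
  gt_all <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    jit <- with_seed(derive_seed(seed, s, 9999),
                     rnorm(nrow(off), 0, base_spec$subject_sd_latency))
    sets <- list()
    gts <- list()
    for (ci in seq_len(nrow(off))) {
      w <- base_spec$effect_window + off$offset_ms[ci] + round(jit[ci])
      # keep the jittered window inside the analysis span
      w <- w - max(0, w[2] - 2000) - min(0, w[1])
      spec_ci <- base_spec
      spec_ci$effect_window <- w
      spec_ci$age <- ages[s]
      spec_ci$seed <- derive_seed(seed, s, ci)
      cell <- paste(off$phase[ci], off$attended_feature[ci],
                    off$context_feature[ci], sep = ".")
      sets[[cell]] <- generate_subject_epochs(
        spec_ci, phase = off$phase[ci],
        attended_feature = off$attended_feature[ci],
        context_feature = off$context_feature[ci], subject_id = sid)
      gts[[cell]] <- data.frame(
        subject_id = sid, age = ages[s], phase = off$phase[ci],
        attended_feature = off$attended_feature[ci],
        context_feature = off$context_feature[ci],
        offset_ms = off$offset_ms[ci], jitter_ms = round(jit[ci]),
        window_start = w[1], window_end = w[2], stringsAsFactors = FALSE)
    }
    gt <- do.call(rbind, gts)
    rownames(gt) <- NULL
    subjects[[s]] <- list(subject_id = sid, age = ages[s], epochs = sets,
                          ground_truth = gt)
    gt_all[[s]] <- gt
  }
  gt_all <- do.call(rbind, gt_all)
  rownames(gt_all) <- NULL
  list(subjects = subjects, ground_truth = gt_all)
}

#' Specification of simulated context-memory responses
#'
#' @param n_match_trials,n_mismatch_trials trial counts for matching and
#'   mismatching test contexts.
#' @param p_match_given_match,p_match_given_mismatch probabilities of a
#'   "match" response given each context status.
#' @param seed integer seed.
#' @return a validated `behavioral_sim_spec` list.
#' @export
behavioral_sim_spec <- function(n_match_trials, n_mismatch_trials,
                                p_match_given_match, p_match_given_mismatch,
                                seed = 1) {
  if (n_match_trials <= 0 || n_mismatch_trials <= 0)
    stopf("trial counts must be positive")
  p <- c(p_match_given_match, p_match_given_mismatch)
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  structure(list(n_match_trials = n_match_trials,
                 n_mismatch_trials = n_mismatch_trials,
                 p_match_given_match = p_match_given_match,
                 p_match_given_mismatch = p_match_given_mismatch,
                 seed = seed),
            class = "behavioral_sim_spec")
}

#' Simulate context-memory match/mismatch responses
#'
#' Bernoulli "match" responses at the specified rates for matching and
#' mismatching test contexts; feeds [context_dprime()].
#'
#' @param spec a [behavioral_sim_spec()].
#' @param feature,role,attention metadata columns copied into the table.
#' @return a behavioral table (data frame with one row per trial).
#' @export
generate_behavioral_responses <- function(spec, feature = "color",
                                          role = "target",
                                          attention = "color") {
  stopifnot(inherits(spec, "behavioral_sim_spec"))
  with_seed(spec$seed, {
    status <- c(rep("match", spec$n_match_trials),
                rep("mismatch", spec$n_mismatch_trials))
    p <- ifelse(status == "match", spec$p_match_given_match,
                spec$p_match_given_mismatch)
    resp <- ifelse(runif(length(p)) < p, "match", "mismatch")
    data.frame(feature = feature, role = role, attention = attention,
               item_status = "old", item_response = "old",
               context_status = status, context_response = resp,
               stringsAsFactors = FALSE)
  })
}
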