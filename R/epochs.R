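#' Epoched EEG container
#'
#' An `epoch_set` holds a trials x channels x samples array of epoched EEG in
#' microvolts together with its time axis and per-trial metadata. Time is
#' always expressed in milliseconds relative to stimulus onset; `t0_offset`
#' gives the time of the first sample (e.g. -1000 for an epoch running from
#' -1000 to +3000 ms).
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param t0_offset time of the first sample in ms relative to stimulus onset.
#' @param channel_names unique channel labels (extended 10-20 system).
#' @param channel_roles `"head"` or `"eog"` per channel.
#' @param trial_labels data frame with one row per trial; expected columns
#'   include `phase`, `attended_feature`, `context_feature`, `outcome`,
#'   `context_identity`, `subject_id` (missing ones are filled with `NA`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, t0_offset, channel_names,
                      channel_roles = NULL, trial_labels = NULL) {
  if (length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array (trials x channels x samples)")
  if (anyNA(data)) stopf("`data` must not contain missing values")
  n_tr <- dim(data)[1]; n_ch <- dim(data)[2]
  if (length(channel_names) != n_ch)
    stopf("%d channel names for %d channels", length(channel_names), n_ch)
  if (anyDuplicated(channel_names)) stopf("channel names must be unique")
  if (is.null(channel_roles)) channel_roles <- rep("head", n_ch)
  if (!all(channel_roles %in% c("head", "eog")))
    stopf("channel roles must be 'head' or 'eog'")
  if (is.null(trial_labels)) trial_labels <- data.frame(row.names = seq_len(n_tr))
  if (nrow(trial_labels) != n_tr)
    stopf("trial_labels has %d rows for %d trials", nrow(trial_labels), n_tr)
  for (col in c("phase", "attended_feature", "context_feature", "outcome",
                "context_identity", "subject_id")) {
    if (is.null(trial_labels[[col]])) trial_labels[[col]] <- NA
  }
  structure(
    list(data = data, sampling_rate = sampling_rate, t0_offset = t0_offset,
         channel_names = as.character(channel_names),
         channel_roles = as.character(channel_roles),
         trial_labels = trial_labels),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  dur <- d[3] / x$sampling_rate * 1000
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              d[1], d[2], d[3], x$sampling_rate, x$t0_offset,
              x$t0_offset + dur - 1000 / x$sampling_rate))
  if (!all(is.na(x$trial_labels$outcome))) {
    tab <- table(x$trial_labels$outcome)
    cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

n_trials  <- function(epochs) dim(epochs$data)[1]
n_channels <- function(epochs) dim(epochs$data)[2]
n_samples <- function(epochs) dim(epochs$data)[3]

#' Sample times of an epoch set
#'
#' @param epochs an `epoch_set`.
#' @return numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_offset + (seq_len(n_samples(epochs)) - 1) / epochs$sampling_rate * 1000
}

# Subset trials, keeping labels aligned and order untouched.
subset_trials <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_labels <- epochs$trial_labels[keep, , drop = FALSE]
  rownames(epochs$trial_labels) <- NULL
  epochs
}

#' Write / read an epoch set as a documented plain-text directory
#'
#' The container is a directory holding `meta.yaml` (sampling rate, time
#' origin, channel names/roles), `labels.tsv` (one row per trial),
#' `data.tsv` (one row per trial x channel, samples across columns) and, when
#' present, the simulator's `ground_truth.tsv` sidecar.
#'
#' @param epochs an `epoch_set`.
#' @param dir directory to create/read.
#' @return `write_epoch_set` returns `dir` invisibly; `read_epoch_set` an
#'   `epoch_set`.
#' @export
write_epoch_set <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sampling_rate = epochs$sampling_rate,
               t0_offset = epochs$t0_offset,
               channel_names = epochs$channel_names,
               channel_roles = epochs$channel_roles,
               n_trials = n_trials(epochs),
               n_samples = n_samples(epochs))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  utils::write.table(epochs$trial_labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  utils::write.table(cbind(trial = rep(seq_len(d[1]), each = d[2]),
                           channel = rep(epochs$channel_names, d[1]),
                           signif(flat, 8)),
                     file.path(dir, "data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("trial", "channel",
                                   paste0("s", seq_len(d[3]))))
  gt <- attr(epochs, "ground_truth")
  if (!is.null(gt))
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  raw <- utils::read.delim(file.path(dir, "data.tsv"), stringsAsFactors = FALSE)
  flat <- as.matrix(raw[, -(1:2), drop = FALSE])
  d <- c(meta$n_trials, length(meta$channel_names), meta$n_samples)
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  out <- epoch_set(data, meta$sampling_rate, meta$t0_offset,
                   unlist(meta$channel_names), unlist(meta$channel_roles),
                   labels)
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path))
    attr(out, "ground_truth") <- utils::read.delim(gt_path,
                                                   stringsAsFactors = FALSE)
  out
}

# The 32-electrode montage used throughout (extended 10-20 names).
montage32 <- c("AF3", "AF4", "FC1", "FC2", "FC5", "FC6", "FP1", "FP2",
               "F7", "F3", "Fz", "F4", "F8", "C3", "Cz", "C4",
               "CP1", "CP2", "CP5", "CP6", "P7", "PO3", "PO4", "P3",
               "Pz", "P4", "P8", "T7", "T8", "O1", "Oz", "O2")
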