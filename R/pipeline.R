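#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' 300-ms windows stepped 20 ms over 0-2000 ms (86 windows), the five
#' oscillatory bands, 5 Fisher-selected features, 5-fold cross-validation,
#' 500 label permutations, 95th-percentile conservative threshold, 60-ms
#' peak neighborhood, and the -300..-100-ms baseline interval. Any override
#' is recorded in the `overrides` field and carried into the provenance
#' manifest.
#'
#' @param ... named overrides of the defaults.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    span = c(0, 2000), window_length = 300, step = 20,
    bands = band_table(), n_features = 5, k_folds = 5,
    n_perm = 500, neighborhood = 60, percentile = 0.95,
    baseline = c(-300, -100), reject = TRUE,
    shrinkage = 0.1, freqs = seq(3, 80, length.out = 78), cycles = 5,
    target_rate = 50.25, engine = "cpp", alpha = 0.05, seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  cfg$overrides <- overrides
  structure(cfg, class = "analysis_config")
}

config_grid <- function(config)
  build_window_grid(config$span, config$window_length, config$step)

#' Decode one subject-condition analysis end to end
#'
#' Baseline correction, optional artifact rejection, Morlet decomposition,
#' time-resolved decoding, permutation null, and earliest-peak extraction
#' for a single epoch set with binary outcome labels.
#'
#' @param epochs an [epoch_set()] whose `trial_labels$outcome` holds the two
#'   classes.
#' @param config an [analysis_config()].
#' @param seed analysis seed (folds and permutations derive from it).
#' @param descriptor optional descriptor list attached to the timecourse.
#' @return list with `timecourse`, `null`, `peak`, `difference`,
#'   `rejection`.
#' @export
run_subject_analysis <- function(epochs, config = analysis_config(),
                                 seed = config$seed, descriptor = NULL) {
  epochs <- baseline_correct(epochs, config$baseline)
  rejection <- NULL
  if (isTRUE(config$reject)) {
    rej <- reject_epochs(epochs)
    epochs <- rej$epochs
    rejection <- rej$report
  }
  tfr <- morlet_tfr(epochs, freqs = config$freqs, cycles = config$cycles,
                    crop = config$span, target_rate = config$target_rate)
  grid <- config_grid(config)
  wbc <- windowed_band_covs(tfr, grid, config$bands)
  labels <- epochs$trial_labels$outcome
  tc <- sliding_window_decode(wbc, labels, grid, config$bands,
                              k_folds = config$k_folds,
                              seed = derive_seed(seed, 1),
                              n_select = config$n_features,
                              shrinkage = config$shrinkage,
                              engine = config$engine, descriptor = descriptor)
  null <- permutation_null(wbc, labels, grid, config$bands,
                           n_perm = config$n_perm, k_folds = config$k_folds,
                           seed = derive_seed(seed, 2),
                           n_select = config$n_features,
                           shrinkage = config$shrinkage,
                           percentile = config$percentile,
                           engine = config$engine)
  peak <- find_earliest_peak(tc, null$conservative_threshold,
                             config$neighborhood)
  list(timecourse = tc, null = null, peak = peak,
       difference = real_minus_chance(tc, null), rejection = rejection)
}

#' Decode every condition cell of a simulated cohort
#'
#' Runs [run_subject_analysis()] for each subject and condition cell and
#' assembles the peak table (one earliest significant peak per subject x
#' phase x attention condition x context feature).
#'
#' @param cohort a [generate_cohort()] result.
#' @param config an [analysis_config()].
#' @param seed cohort-level seed.
#' @return list with `peaks` (data frame), `analyses` (nested results),
#'   `config`.
#' @export
run_cohort_decoding <- function(cohort, config = analysis_config(),
                                seed = config$seed) {
  rows <- list()
  analyses <- list()
  for (s in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[s]]
    for (cell in names(subj$epochs)) {
      ep <- subj$epochs[[cell]]
      lab <- ep$trial_labels[1, ]
      res <- run_subject_analysis(
        ep, config, seed = derive_seed(seed, s, match(cell, names(subj$epochs))),
        descriptor = list(subject = subj$subject_id, phase = lab$phase,
                          attended = lab$attended_feature,
                          feature = lab$context_feature))
      analyses[[subj$subject_id]][[cell]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subj$subject_id, age = subj$age, phase = lab$phase,
        attended_feature = lab$attended_feature,
        context_feature = lab$context_feature,
        midpoint_ms = res$peak$midpoint_ms,
        accuracy_pct = res$peak$accuracy_pct,
        significant = res$peak$is_significant,
        threshold_pct = res$null$conservative_threshold,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  list(peaks = peaks, analyses = analyses, config = config)
}

peak_of <- function(peaks, phase, attended, feature) {
  sel <- peaks$phase == phase & peaks$attended_feature == attended &
    peaks$context_feature == feature
  out <- peaks[sel, c("subject_id", "midpoint_ms", "significant")]
  ifelse(out$significant, out$midpoint_ms, NA_real_)[order(out$subject_id)]
}

#' Latency-ordering contrasts for one phase
#'
#' Builds the one-tailed Wilcoxon contrasts that feed [model_verdict()]:
#' the prioritized-feature-first contrast when the prioritized feature is
#' attended and when it is not (plus the reverse direction), the
#' interaction of attention on the latency gap, and the attended-prioritized
#' vs attended-other contrast. Subjects lacking a significant peak in a
#' needed cell are dropped pairwise.
#'
#' @param peaks peak table from [run_cohort_decoding()].
#' @param phase `"encoding"` or `"retrieval"`.
#' @param prioritized the feature expected earlier in this phase
#'   (conventionally color at encoding, scene at retrieval).
#' @param other the competing feature.
#' @return named list of `group_test` objects (`attended`, `unattended`,
#'   `unattended_reversed`, `interaction`, `across`).
#' @export
latency_contrasts <- function(peaks, phase, prioritized = "color",
                              other = "scene") {
  pk <- peaks[peaks$phase == phase, , drop = FALSE]
  pri_att_pri <- peak_of(pk, phase, prioritized, prioritized)
  pri_att_oth <- peak_of(pk, phase, prioritized, other)
  oth_att_pri <- peak_of(pk, phase, other, prioritized)
  oth_att_oth <- peak_of(pk, phase, other, other)
  list(
    attended = wilcoxon_one_tailed(pri_att_pri, pri_att_oth, "x<y"),
    unattended = wilcoxon_one_tailed(oth_att_pri, oth_att_oth, "x<y"),
    unattended_reversed = wilcoxon_one_tailed(oth_att_pri, oth_att_oth, "x>y"),
    interaction = wilcoxon_one_tailed(pri_att_oth - pri_att_pri,
                                      oth_att_oth - oth_att_pri, "x>y"),
    across = wilcoxon_one_tailed(pri_att_pri, oth_att_oth, "x<y"))
}

#' Full group-level battery over a peak table
#'
#' KS normality screen on the pooled peaks, per-phase latency contrasts and
#' model verdicts, and age regressions on each condition's peaks.
#'
#' @param peaks peak table from [run_cohort_decoding()].
#' @param alpha significance level for the verdicts.
#' @param prioritized named character: prioritized feature per phase.
#' @return list with `normality`, `contrasts`, `verdicts`,
#'   `age_regressions`.
#' @export
group_battery <- function(peaks, alpha = 0.05,
                          prioritized = c(encoding = "color",
                                          retrieval = "scene")) {
  normality <- ks_normality(peaks$midpoint_ms[peaks$significant])
  phases <- intersect(names(prioritized), unique(peaks$phase))
  contrasts <- list(); verdicts <- list()
  for (ph in phases) {
    pri <- prioritized[[ph]]
    oth <- setdiff(unique(peaks$context_feature), pri)[1]
    ctr <- latency_contrasts(peaks, ph, pri, oth)
    contrasts[[ph]] <- ctr
    verdicts[[ph]] <- model_verdict(ctr, alpha = alpha, phase = ph)
  }
  cells <- unique(peaks[, c("phase", "attended_feature", "context_feature")])
  age_regs <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- peaks$phase == cells$phase[i] &
      peaks$attended_feature == cells$attended_feature[i] &
      peaks$context_feature == cells$context_feature[i] & peaks$significant
    if (sum(sel) >= 3 && sd(peaks$age[sel]) > 0) {
      nm <- paste(cells$phase[i], cells$attended_feature[i],
                  cells$context_feature[i], sep = ".")
      age_regs[[nm]] <- age_regression(peaks$midpoint_ms[sel],
                                       peaks$age[sel])
    }
  }
  list(normality = normality, contrasts = contrasts, verdicts = verdicts,
       age_regressions = age_regs)
}

#' Run the complete pipeline over a directory of epoch sets
#'
#' Reads every epoch-set subdirectory under `input_dir` (see
#' [write_epoch_set()]), decodes each subject-condition analysis, and
#' writes per-analysis timecourses, the peak table, group statistics,
#' verdicts, and a provenance manifest (config, overrides, seed, package
#' version) under `output_dir`.
#'
#' @param input_dir directory of epoch-set subdirectories.
#' @param output_dir results directory (created).
#' @param config an [analysis_config()].
#' @return the [group_battery()] result plus the peak table, invisibly.
#' @export
run_full_pipeline <- function(input_dir, output_dir,
                              config = analysis_config()) {
  sets <- list.dirs(input_dir, recursive = FALSE)
  if (length(sets) == 0) stopf("no epoch-set directories under %s", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(sets)) {
    ep <- read_epoch_set(sets[i])
    lab <- ep$trial_labels[1, ]
    res <- run_subject_analysis(ep, config, seed = derive_seed(config$seed, i))
    tag <- basename(sets[i])
    utils::write.table(
      data.frame(midpoint_ms = res$timecourse$midpoint_ms,
                 accuracy_pct = res$timecourse$accuracy_pct,
                 difference_pct = res$difference$difference_pct),
      file.path(output_dir, paste0(tag, "_timecourse.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[i]] <- data.frame(
      subject_id = lab$subject_id, age = lab$age %||% NA, phase = lab$phase,
      attended_feature = lab$attended_feature,
      context_feature = lab$context_feature,
      midpoint_ms = res$peak$midpoint_ms,
      accuracy_pct = res$peak$accuracy_pct,
      significant = res$peak$is_significant,
      threshold_pct = res$null$conservative_threshold,
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  utils::write.table(peaks, file.path(output_dir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  battery <- tryCatch(group_battery(peaks, alpha = config$alpha),
                      error = function(e) NULL)
  if (!is.null(battery)) {
    stats_rows <- do.call(rbind, lapply(names(battery$contrasts), function(ph) {
      do.call(rbind, lapply(names(battery$contrasts[[ph]]), function(nm) {
        gt <- battery$contrasts[[ph]][[nm]]
        data.frame(phase = ph, contrast = nm,
                   statistic = unname(gt$statistic[1]), p = gt$p, n = gt$n)
      }))
    }))
    utils::write.table(stats_rows, file.path(output_dir, "group_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    verdicts <- vapply(battery$verdicts, function(v) v$verdict, "")
    utils::write.table(data.frame(phase = names(verdicts), verdict = verdicts),
                       file.path(output_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "oscmvpa",
    version = as.character(utils::packageVersion("oscmvpa")),
    seed = config$seed,
    n_analyses = length(sets),
    config = config[setdiff(names(config), c("overrides", "bands", "freqs"))],
    overrides = config$overrides,
    config_hash = sum(utils::head(
      utf8ToInt(paste(deparse(config[order(names(config))]), collapse = "")),
      10000)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(peaks = peaks, battery = battery, manifest = manifest))
}
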