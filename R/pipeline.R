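## End-to-end composition: configuration, the single-recording pipeline,
## and the pooled multi-subject study.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the standard protocol
#' defaults: 300 s windows sliding by 10 s, 120 s scenario buffers, 20%
#' per-tail envelope trimming, 4 Hz resampling, the LF/HF band presets and
#' a degree-3, C = 1 polynomial SVM.
#'
#' @param window_s,step_s Sliding-window length and increment, seconds.
#' @param buffer_s Seconds masked at both ends of every labeled segment.
#' @param trim Per-tail trim fraction of the envelope means.
#' @param fs_hz Uniform resampling rate, Hz.
#' @param peak_threshold,peak_context Sharp-peak removal rule (fractional
#'   deviation from the running median; context width in beats).
#' @param svm_degree,svm_cost Polynomial-kernel SVM hyperparameters.
#' @param seed Seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_s = 300, step_s = 10, buffer_s = 120,
                       trim = 0.2, fs_hz = 4, peak_threshold = 0.3,
                       peak_context = 11L, svm_degree = 3, svm_cost = 1,
                       seed = 0L) {
  stopifnot(window_s > 0, step_s > 0, buffer_s >= 0, trim >= 0, trim < 0.5,
            fs_hz > 0.8, svm_degree >= 1, svm_cost > 0)
  structure(list(window_s = window_s, step_s = step_s, buffer_s = buffer_s,
                 trim = trim, fs_hz = fs_hz,
                 peak_threshold = peak_threshold,
                 peak_context = as.integer(peak_context),
                 svm_degree = svm_degree, svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

## Preprocess + envelopes + per-window features for one recording.
extract_features <- function(beats, segments = NULL, config = run_config(),
                             clean = TRUE) {
  if (clean) beats <- remove_sharp_peaks(beats, config$peak_threshold,
                                         config$peak_context)
  tg <- resample_uniform(beats, fs_hz = config$fs_hz)
  env_lf <- hilbert_envelope(bandpass_filter(tg, lf_band()))
  env_hf <- hilbert_envelope(bandpass_filter(tg, hf_band()))
  grid <- sliding_windows(tg$time_s[1], tg$time_s[nrow(tg)],
                          length_s = config$window_s, step_s = config$step_s)
  window_features(tg, grid, env_lf, env_hf, segments = segments,
                  buffer_s = config$buffer_s, trim = config$trim)
}

#' Run the full analysis pipeline on one recording
#'
#' Reads (or accepts) a beat series and optional scenario labels, removes
#' sharp peaks, resamples, extracts per-window band powers and
#' instantaneous amplitudes, and -- when at least two labeled scenarios
#' are present -- fits the 2D instantaneous-amplitude categorizer and
#' reports its accuracy, confusion counts and pairwise rank-sum p-values.
#'
#' @param rr Path to an RR file, or a [beat_series()].
#' @param labels Path to a segment CSV, or a segment tibble, or `NULL`.
#' @param config A [run_config()].
#' @param verbose Log the resolved configuration and stage progress?
#' @return A list of class `hrv_report` with elements `features`
#'   (tibble), `config`, and -- when labels allow -- `model`
#'   (`hrv_categorizer`), `ca_pct`, `confusion`, `p_values`.
#' @export
run_pipeline <- function(rr, labels = NULL, config = run_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (verbose) {
    say("resolved configuration:")
    for (nm in names(config)) say("  %-14s %s", nm, format(config[[nm]]))
  }
  beats <- if (is.character(rr)) read_rr(rr) else as_beat_series(rr)
  segments <- if (is.character(labels)) read_labels(labels)
  else if (!is.null(labels)) validate_segments(as_tibble(labels))
  say("stage preprocess+features: %d beats", nrow(beats))
  features <- extract_features(beats, segments, config)
  out <- list(features = features, config = config)
  class_sizes <- table(features$label[!is.na(features$label)])
  if (!is.null(segments) && length(class_sizes) >= 2 &&
      all(class_sizes >= 3)) {
    say("stage categorize: %d labeled windows", sum(!is.na(features$label)))
    model <- fit_categorizer_2d(features, "LFiA_ms", "HFiA_ms",
                                degree = config$svm_degree,
                                cost = config$svm_cost)
    out$model <- model
    out$ca_pct <- categorization_accuracy(model)
    out$confusion <- confusion_counts(model)
    labs <- unique(stats::na.omit(features$label))
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    out$p_values <- purrr::map_dfr(pairs, function(p) {
      a <- features$HFiA_ms[features$label == p[1]]
      b <- features$HFiA_ms[features$label == p[2]]
      tibble(scenario_a = p[1], scenario_b = p[2],
             p_HFiA = wilcoxon_scenarios(a, b))
    })
  }
  structure(out, class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("<hrv_report> %d feature windows\n", nrow(x$features)))
  if (!is.null(x$ca_pct))
    cat(sprintf("  2D-iA categorization accuracy: %.1f%%\n", x$ca_pct))
  invisible(x)
}

#' @method glance hrv_report
#' @export
glance.hrv_report <- function(x, ...) {
  tibble(n_windows = nrow(x$features),
         n_labeled = sum(!is.na(x$features$label)),
         ca_pct = if (is.null(x$ca_pct)) NA_real_ else x$ca_pct)
}

#' Simulate and analyze the pooled standardized-protocol study
#'
#' The package's headline computation: simulate a cohort under the
#' rest/math/rest/exercise/rest protocol ([simulate_part1_cohort()]), run
#' the per-subject pipeline, pool the windows of the scenarios of
#' interest, standardize each subject by their first-rest median, then
#' score every univariate metric and both 2D representations by
#' categorization accuracy, plus per-subject-mean rank-sum p-values per
#' scenario pair.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed for the whole study.
#' @param scenarios Labels entering the categorization.
#' @param config A [run_config()].
#' @param clean Apply sharp-peak removal before analysis?
#' @return A list of class `part1_study`: `features` (pooled standardized
#'   windows), `ca` (tibble metric/dimensionality/CA), `p_values`,
#'   `models` (the fitted categorizers).
#' @export
run_part1_study <- function(n_subjects = 10, seed = 0L,
                            scenarios = c("Rest 1", "Math", "Exercise"),
                            config = run_config(), clean = TRUE) {
  cohort <- simulate_part1_cohort(n_subjects = n_subjects, seed = seed)
  feats <- purrr::map2_dfr(cohort$beats, cohort$subject_id,
                           function(b, id) {
                             seg <- cohort$segments[[match(id, cohort$subject_id)]]
                             f <- extract_features(b, seg, config, clean = clean)
                             f$subject_id <- id
                             f
                           })
  feats <- dplyr::filter(feats, .data$label %in% scenarios)
  metric_cols <- c("LFp_ms2", "HFp_ms2", "ratio_p", "LFn", "HFn",
                   "LFiA_ms", "HFiA_ms", "ratio_iA")
  std <- standardize_by_baseline(feats, scenarios[1],
                                 feature_cols = metric_cols)
  fit1 <- function(col) fit_categorizer_1d(std, col,
                                           degree = config$svm_degree,
                                           cost = config$svm_cost)
  fit2 <- function(cx, cy) fit_categorizer_2d(std, cx, cy,
                                              degree = config$svm_degree,
                                              cost = config$svm_cost)
  models <- list(
    LFp = fit1("LFp_ms2"), HFp = fit1("HFp_ms2"), ratio_p = fit1("ratio_p"),
    LFn = fit1("LFn"), HFn = fit1("HFn"),
    LFiA = fit1("LFiA_ms"), HFiA = fit1("HFiA_ms"),
    ratio_iA = fit1("ratio_iA"),
    `2D_p` = fit2("LFp_ms2", "HFp_ms2"),
    `2D_n` = fit2("LFn", "HFn"),
    `2D_iA` = fit2("LFiA_ms", "HFiA_ms"))
  ca <- purrr::imap_dfr(models, function(m, nm) {
    tibble(metric = nm, dims = if (m$mode == "2d") 2L else 1L,
           ca_pct = categorization_accuracy(m))
  })
  subj_means <- std |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  pairs <- utils::combn(scenarios, 2, simplify = FALSE)
  p_values <- purrr::map_dfr(pairs, function(p) {
    purrr::map_dfr(metric_cols, function(col) {
      a <- subj_means[[col]][subj_means$label == p[1]]
      b <- subj_means[[col]][subj_means$label == p[2]]
      tibble(metric = col, scenario_a = p[1], scenario_b = p[2],
             p = wilcoxon_scenarios(a, b))
    })
  })
  structure(list(features = std, ca = ca, p_values = p_values,
                 models = models, config = config, seed = seed,
                 n_subjects = n_subjects),
            class = "part1_study")
}

#' @export
print.part1_study <- function(x, ...) {
  cat(sprintf("<part1_study> %d subjects, %d pooled windows\n",
              x$n_subjects, nrow(x$features)))
  cat("categorization accuracy (resubstitution, %):\n")
  df <- as.data.frame(x$ca)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @method tidy part1_study
#' @export
tidy.part1_study <- function(x, ...) x$ca

#' @method glance part1_study
#' @export
glance.part1_study <- function(x, ...) {
  best1 <- max(x$ca$ca_pct[x$ca$dims == 1])
  tibble(n_subjects = x$n_subjects,
         n_windows = nrow(x$features),
         ca_2d_ia_pct = x$ca$ca_pct[x$ca$metric == "2D_iA"],
         best_1d_pct = best1,
         best_1d_metric = x$ca$metric[x$ca$dims == 1][
           which.max(x$ca$ca_pct[x$ca$dims == 1])])
}
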