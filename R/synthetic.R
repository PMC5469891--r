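## Synthetic NN-interval simulator: scenario specs, tachogram model,
## beat-time accumulation, artifact injection, and protocol presets.

#' Describe one synthetic recording scenario
#'
#' A scenario is a stationary-in-the-mean segment of a simulated recording:
#' the NN interval fluctuates around `mean_nni_ms` with one sinusoidal
#' oscillation in the LF band (0.04--0.15 Hz) and one in the HF band
#' (0.15--0.4 Hz), plus white Gaussian noise.  Optionally the two band
#' amplitudes are slowly modulated (`drift_lf`, `drift_hf`) to emulate the
#' nonstationarity of real recordings; with the default drift of 0 the
#' generated interval function is exactly
#' `mean_nni_ms + amp_lf_ms*sin(2*pi*freq_lf_hz*t) +
#'  amp_hf_ms*sin(2*pi*freq_hf_hz*t) + noise`.
#'
#' @param label Scenario label (e.g. `"Rest 1"`).
#' @param duration_s Segment duration in seconds (> 0).
#' @param mean_nni_ms Mean NN interval in milliseconds (> 0).
#' @param amp_lf_ms,amp_hf_ms Peak amplitudes of the LF and HF oscillations
#'   in milliseconds (>= 0).
#' @param freq_lf_hz LF oscillation frequency, in `[0.04, 0.15)` Hz.
#' @param freq_hf_hz HF oscillation frequency, in `[0.15, 0.4]` Hz.
#' @param noise_sd_ms Standard deviation of additive white Gaussian noise on
#'   the interval function, milliseconds.
#' @param drift_lf,drift_hf Fractional depth of a slow sinusoidal amplitude
#'   modulation of each band (0 disables it).
#' @param drift_freq_hz Frequency of the amplitude modulation; the default
#'   6e-4 Hz (period ~28 min) is well below the LF band edge.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("Rest", 300, mean_nni_ms = 850, amp_lf_ms = 38,
#'               freq_lf_hz = 0.09, amp_hf_ms = 40, freq_hf_hz = 0.25)
#' @export
scenario_spec <- function(label, duration_s, mean_nni_ms = 850,
                          amp_lf_ms = 30, freq_lf_hz = 0.1,
                          amp_hf_ms = 30, freq_hf_hz = 0.25,
                          noise_sd_ms = 0,
                          drift_lf = 0, drift_hf = 0, drift_freq_hz = 6e-4) {
  stopifnot(is.character(label), length(label) == 1L)
  if (duration_s <= 0) abort("`duration_s` must be > 0")
  if (mean_nni_ms <= 0) abort("`mean_nni_ms` must be > 0")
  if (amp_lf_ms < 0 || amp_hf_ms < 0 || noise_sd_ms < 0)
    abort("amplitudes and `noise_sd_ms` must be >= 0")
  if (freq_lf_hz < 0.04 || freq_lf_hz >= 0.15)
    abort("`freq_lf_hz` must lie in [0.04, 0.15)")
  if (freq_hf_hz < 0.15 || freq_hf_hz > 0.4)
    abort("`freq_hf_hz` must lie in [0.15, 0.4]")
  if (drift_lf < 0 || drift_lf >= 1 || drift_hf < 0 || drift_hf >= 1)
    abort("drift depths must lie in [0, 1)")
  # worst-case excursion must keep intervals positive
  if (amp_lf_ms * (1 + drift_lf) + amp_hf_ms * (1 + drift_hf) +
      4 * noise_sd_ms >= mean_nni_ms)
    abort("amp_lf + amp_hf + 4*noise_sd must stay below mean_nni (intervals must stay positive)")
  structure(
    list(label = label, duration_s = duration_s, mean_nni_ms = mean_nni_ms,
         amp_lf_ms = amp_lf_ms, freq_lf_hz = freq_lf_hz,
         amp_hf_ms = amp_hf_ms, freq_hf_hz = freq_hf_hz,
         noise_sd_ms = noise_sd_ms,
         drift_lf = drift_lf, drift_hf = drift_hf,
         drift_freq_hz = drift_freq_hz),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: %gs, mean NNI %g ms, LF %g ms @ %g Hz, HF %g ms @ %g Hz, noise %g ms\n",
    x$label, x$duration_s, x$mean_nni_ms, x$amp_lf_ms, x$freq_lf_hz,
    x$amp_hf_ms, x$freq_hf_hz, x$noise_sd_ms))
  invisible(x)
}

#' Describe an injectable artifact
#'
#' @param kind One of `"deep_breath"`, `"ectopic"`, `"bradycardia"`.
#'   Deep breaths and transient bradycardia add a smooth unimodal
#'   lengthening of the NN intervals (lower heart rate); an ectopic beat
#'   rescales one interval by 0.6 and its successor by 1.4 (a compensated
#'   premature beat).
#' @param onset_s Artifact onset in seconds from the start of the recording.
#' @param duration_s Artifact duration in seconds (ignored for `"ectopic"`,
#'   which affects exactly two beats).
#' @param magnitude_ms Peak interval excursion in milliseconds (ignored for
#'   `"ectopic"`).
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("deep_breath", "ectopic", "bradycardia"),
                          onset_s, duration_s = 10, magnitude_ms = 300) {
  kind <- match.arg(kind)
  if (onset_s < 0) abort("`onset_s` must be >= 0")
  if (duration_s <= 0) abort("`duration_s` must be > 0")
  if (magnitude_ms < 0) abort("`magnitude_ms` must be >= 0")
  structure(list(kind = kind, onset_s = onset_s, duration_s = duration_s,
                 magnitude_ms = magnitude_ms),
            class = "artifact_spec")
}

#' Describe a full recording protocol
#'
#' An ordered sequence of [scenario_spec()] segments plus a list of
#' [artifact_spec()]s, with a seed that makes the generated recording fully
#' reproducible.
#'
#' @param segments List of [scenario_spec()] objects, in order.
#' @param artifacts Optional list of [artifact_spec()] objects; onsets are
#'   relative to the start of the whole recording.
#' @param seed Integer seed for all randomness in the generated recording.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(segments, artifacts = list(), seed = 0L) {
  if (length(segments) == 0)
    abort("`segments` must be non-empty")
  ok <- vapply(segments, inherits, logical(1), "scenario_spec")
  if (!all(ok)) abort("all `segments` must be scenario_spec objects")
  ok <- vapply(artifacts, inherits, logical(1), "artifact_spec")
  if (length(artifacts) && !all(ok))
    abort("all `artifacts` must be artifact_spec objects")
  total <- sum(vapply(segments, `[[`, numeric(1), "duration_s"))
  for (a in artifacts)
    if (a$onset_s >= total)
      abort("artifact onset beyond the end of the protocol")
  structure(list(segments = segments, artifacts = artifacts,
                 seed = as.integer(seed)),
            class = "protocol_spec")
}

## Deterministic part of the interval model.  Drift phases are drawn from
## the current RNG stream (only when a drift depth is non-zero), so a seeded
## caller gets reproducible drift.
nni_modulator <- function(spec) {
  ph_lf <- if (spec$drift_lf > 0) runif(1, 0, 2 * pi) else 0
  ph_hf <- if (spec$drift_hf > 0) runif(1, 0, 2 * pi) else 0
  force(spec)
  function(t) {
    a_lf <- spec$amp_lf_ms *
      (1 + spec$drift_lf * sin(2 * pi * spec$drift_freq_hz * t + ph_lf))
    a_hf <- spec$amp_hf_ms *
      (1 + spec$drift_hf * sin(2 * pi * spec$drift_freq_hz * t + ph_hf))
    spec$mean_nni_ms +
      a_lf * sin(2 * pi * spec$freq_lf_hz * t) +
      a_hf * sin(2 * pi * spec$freq_hf_hz * t)
  }
}

#' Sample the ground-truth interval function of a scenario
#'
#' Evaluates the modulating NN-interval function of a scenario on an
#' arbitrary time grid.  With `noise_sd_ms = 0` and zero drift the result
#' equals the closed-form two-tone model to machine precision, which makes
#' this the oracle for every downstream spectral test.
#'
#' @param spec A [scenario_spec()].
#' @param t_grid Strictly increasing times in seconds, within
#'   `[0, duration_s]`.
#' @param seed Optional seed applied locally (the caller's RNG stream is
#'   restored on exit).
#' @return Numeric vector of NN intervals in milliseconds, one per grid
#'   point.
#' @examples
#' sp <- scenario_spec("x", 10, mean_nni_ms = 1000, amp_lf_ms = 50,
#'                     freq_lf_hz = 0.1, amp_hf_ms = 0)
#' generate_tachogram(sp, c(0, 2.5))  # 1000, 1050
#' @export
generate_tachogram <- function(spec, t_grid, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (length(t_grid) == 0) abort("`t_grid` must be non-empty")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing")
  if (min(t_grid) < 0 || max(t_grid) > spec$duration_s)
    abort("`t_grid` must lie within [0, duration_s]")
  with_local_seed(seed, {
    m <- nni_modulator(spec)
    vals <- m(t_grid)
    if (spec$noise_sd_ms > 0)
      vals <- vals + rnorm(length(t_grid), 0, spec$noise_sd_ms)
    vals
  })
}

#' Generate beat times for one scenario
#'
#' Accumulates beat times by iterating `t[k+1] = t[k] + m(t[k]) / 1000`,
#' where `m` is the (noisy) interval function of the scenario: each interval
#' is the value of the modulating function at the beat that opens it.
#'
#' @inheritParams generate_tachogram
#' @return A [beat_series()] whose last beat does not exceed `duration_s`.
#' @examples
#' b <- tachogram_to_beats(scenario_spec("x", 10, mean_nni_ms = 1000,
#'                                       amp_lf_ms = 0, amp_hf_ms = 0))
#' nrow(b)  # 11 beats at 0, 1, ..., 10 s
#' @export
tachogram_to_beats <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_local_seed(seed, {
    m <- nni_modulator(spec)
    n_guess <- ceiling(spec$duration_s / (spec$mean_nni_ms / 1000)) + 8L
    ts <- numeric(n_guess)
    k <- 1L
    t <- 0
    repeat {
      nni <- m(t)
      if (spec$noise_sd_ms > 0) nni <- nni + rnorm(1, 0, spec$noise_sd_ms)
      if (nni <= 0)
        abort("generated a non-positive interval; scenario invariants violated")
      t_next <- t + nni / 1000
      if (t_next > spec$duration_s) break
      k <- k + 1L
      if (k > length(ts)) ts <- c(ts, numeric(64L))
      ts[k] <- t_next
      t <- t_next
    }
    beat_series(ts[seq_len(k)])
  })
}

#' Inject an artifact into a beat series
#'
#' Deep breaths and bradycardia episodes add a smooth unimodal (raised
#' cosine) excursion with peak `magnitude_ms` to the intervals inside
#' `[onset, onset + duration]`; positive magnitude means longer intervals,
#' i.e. a transiently lower heart rate.  An ectopic beat rescales the
#' interval containing the onset by 0.6 and its successor by 1.4, conserving
#' their sum.  Beat times are re-accumulated from the modified intervals.
#'
#' @param beats A [beat_series()].
#' @param art An [artifact_spec()].
#' @return A [beat_series()] of the same length.
#' @export
inject_artifact <- function(beats, art) {
  beats <- as_beat_series(beats)
  stopifnot(inherits(art, "artifact_spec"))
  iv <- nn_intervals(beats)
  t_end <- beats$beat_s[nrow(beats)]
  if (art$onset_s >= t_end)
    abort("artifact onset lies beyond the end of the recording")
  nni <- iv$nni_ms
  if (art$kind == "ectopic") {
    k <- findInterval(art$onset_s, iv$t_start_s)
    k <- max(1L, min(k, length(nni) - 1L))
    nni[k] <- 0.6 * nni[k]
    nni[k + 1L] <- 1.4 * nni[k + 1L]
  } else if (art$magnitude_ms > 0) {
    mid <- iv$t_mid_s
    inside <- mid >= art$onset_s & mid <= art$onset_s + art$duration_s
    if (any(inside)) {
      shape <- sin(pi * (mid[inside] - art$onset_s) / art$duration_s)^2
      # scale so the realized peak excursion equals magnitude_ms
      nni[inside] <- nni[inside] + art$magnitude_ms * shape / max(shape)
    }
  }
  beats_from_intervals(nni, t0 = beats$beat_s[1])
}

#' Generate a full protocol recording
#'
#' Concatenates the beat series of all segments (each generated from the
#' protocol's seeded RNG stream, so the whole recording is reproducible),
#' shifts them to consecutive start times, applies the protocol's
#' artifacts, and returns the beats together with a segment label table.
#'
#' @param protocol A [protocol_spec()].
#' @return A list with elements `beats` (a [beat_series()]) and `segments`
#'   (a tibble with columns `label`, `start_s`, `end_s`).
#' @examples
#' pr <- part1_protocol(seed = 1)
#' rec <- generate_protocol(pr)
#' rec$segments
#' @export
generate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  durs <- vapply(protocol$segments, `[[`, numeric(1), "duration_s")
  starts <- cumsum(c(0, durs[-length(durs)]))
  labels <- vapply(protocol$segments, `[[`, character(1), "label")
  with_local_seed(protocol$seed, {
    all_beats <- numeric(0)
    for (i in seq_along(protocol$segments)) {
      b <- tachogram_to_beats(protocol$segments[[i]])$beat_s + starts[i]
      if (length(all_beats))
        b <- b[b > all_beats[length(all_beats)]]
      all_beats <- c(all_beats, b)
    }
    beats <- beat_series(all_beats)
    for (a in protocol$artifacts)
      beats <- inject_artifact(beats, a)
    list(beats = beats,
         segments = tibble(label = labels, start_s = starts,
                           end_s = starts + durs))
  })
}

## Frozen scenario archetypes for the standardized mental/physical stress
## protocol.  Effect directions: mental arithmetic raises the LF amplitude
## and lowers the HF amplitude relative to rest; stepper exercise lowers the
## HF amplitude strongly and the mean NNI, with the LF amplitude near the
## resting level.  A slow +-15% amplitude drift emulates the nonstationarity
## of real recordings.
part1_scenarios <- function(duration_s = 900) {
  list(
    rest = function(label) scenario_spec(
      label, duration_s, mean_nni_ms = 850,
      amp_lf_ms = 38, freq_lf_hz = 0.09, amp_hf_ms = 40, freq_hf_hz = 0.25,
      noise_sd_ms = 10, drift_lf = 0.15, drift_hf = 0.15),
    math = function(label) scenario_spec(
      label, duration_s, mean_nni_ms = 750,
      amp_lf_ms = 52, freq_lf_hz = 0.10, amp_hf_ms = 15, freq_hf_hz = 0.25,
      noise_sd_ms = 10, drift_lf = 0.15, drift_hf = 0.15),
    exercise = function(label) scenario_spec(
      label, duration_s, mean_nni_ms = 600,
      amp_lf_ms = 36, freq_lf_hz = 0.08, amp_hf_ms = 15, freq_hf_hz = 0.30,
      noise_sd_ms = 10, drift_lf = 0.15, drift_hf = 0.15))
}

#' The standardized rest/math/rest/exercise/rest protocol preset
#'
#' Five 15-minute segments in the order Rest 1, Math, Rest 2, Exercise,
#' Rest 3, mimicking a standardized mental- and physical-stress session
#' (quiet sitting, competitive mental arithmetic, recovery, stepper
#' exercise, recovery).  A synthetic transient-bradycardia artifact (8 s,
#' 250 ms -- an illustrative placeholder, not an empirical value) is placed
#' in the middle of Rest 3.
#'
#' @param seed Integer seed for the generated recording.
#' @param segment_s Duration of each segment in seconds.
#' @param rest3_bradycardia Include the Rest 3 bradycardia artifact?
#' @return A [protocol_spec()].
#' @export
part1_protocol <- function(seed = 0L, segment_s = 900,
                           rest3_bradycardia = TRUE) {
  sc <- part1_scenarios(segment_s)
  segs <- list(sc$rest("Rest 1"), sc$math("Math"), sc$rest("Rest 2"),
               sc$exercise("Exercise"), sc$rest("Rest 3"))
  arts <- list()
  if (rest3_bradycardia)
    arts <- list(artifact_spec("bradycardia",
                               onset_s = 4 * segment_s + segment_s / 2 - 4,
                               duration_s = 8, magnitude_ms = 250))
  protocol_spec(segs, arts, seed = seed)
}

#' Simulate a cohort of subjects under the standardized protocol
#'
#' Each subject runs the [part1_protocol()] with subject-level random
#' effects: log-normal multipliers (sd 0.2 on the log scale) on the LF and
#' HF amplitudes of *all* their segments, and a Gaussian offset (sd 60 ms)
#' on the mean NN interval.  Inter-subject baseline differences like these
#' are what make pooled one-dimensional features ambiguous and motivate
#' per-subject baseline standardization.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed; subject-level effects and per-subject recording
#'   seeds all derive from it.
#' @param segment_s Duration of each protocol segment in seconds.
#' @param amp_sd_log SD of the log-normal band-amplitude multipliers.
#' @param mean_nni_sd_ms SD of the subject offset on the mean NN interval.
#' @return A tibble with one row per subject: `subject_id`, the realized
#'   multipliers, and list-columns `beats` and `segments`.
#' @export
simulate_part1_cohort <- function(n_subjects = 10, seed = 0L,
                                  segment_s = 900,
                                  amp_sd_log = 0.2, mean_nni_sd_ms = 60) {
  stopifnot(n_subjects >= 1)
  with_local_seed(seed, {
    eff <- tibble(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      lf_mult = exp(rnorm(n_subjects, 0, amp_sd_log)),
      hf_mult = exp(rnorm(n_subjects, 0, amp_sd_log)),
      nni_offset_ms = rnorm(n_subjects, 0, mean_nni_sd_ms),
      rec_seed = sample.int(.Machine$integer.max - 1L, n_subjects))
    recs <- purrr::pmap(eff, function(subject_id, lf_mult, hf_mult,
                                      nni_offset_ms, rec_seed) {
      base <- part1_protocol(seed = rec_seed, segment_s = segment_s)
      segs <- purrr::map(base$segments, function(s) {
        scenario_spec(s$label, s$duration_s,
                      mean_nni_ms = s$mean_nni_ms + nni_offset_ms,
                      amp_lf_ms = s$amp_lf_ms * lf_mult,
                      freq_lf_hz = s$freq_lf_hz,
                      amp_hf_ms = s$amp_hf_ms * hf_mult,
                      freq_hf_hz = s$freq_hf_hz,
                      noise_sd_ms = s$noise_sd_ms,
                      drift_lf = s$drift_lf, drift_hf = s$drift_hf,
                      drift_freq_hz = s$drift_freq_hz)
      })
      generate_protocol(protocol_spec(segs, base$artifacts, seed = rec_seed))
    })
    eff$beats <- purrr::map(recs, "beats")
    eff$segments <- purrr::map(recs, "segments")
    eff
  })
}
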