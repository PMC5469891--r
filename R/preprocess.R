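## Beat-series container, NN-interval derivation, sharp-peak removal and
## uniform resampling.

#' Construct a beat series
#'
#' The raw object of analysis: strictly increasing beat timestamps in
#' seconds.  NN intervals are the successive differences, in milliseconds;
#' see [nn_intervals()].
#'
#' @param beat_s Numeric vector of beat times in seconds, strictly
#'   increasing, length >= 2.
#' @return A tibble of class `beat_series` with column `beat_s`.
#' @export
beat_series <- function(beat_s) {
  beat_s <- as.numeric(beat_s)
  if (length(beat_s) < 2) abort("a beat series needs at least 2 beats")
  if (anyNA(beat_s)) abort("beat times must be finite")
  if (any(diff(beat_s) <= 0))
    abort("beat times must be strictly increasing")
  structure(tibble(beat_s = beat_s),
            class = c("beat_series", class(tibble())))
}

as_beat_series <- function(x) {
  if (inherits(x, "beat_series")) return(x)
  if (is.data.frame(x) && "beat_s" %in% names(x)) return(beat_series(x$beat_s))
  beat_series(x)
}

#' Derive NN intervals from beat timestamps
#'
#' @param beats A [beat_series()] or a numeric vector of strictly
#'   increasing beat times in seconds.
#' @return A tibble with one row per interval: `t_start_s` (opening beat),
#'   `t_mid_s` (interval midpoint) and `nni_ms`.
#' @examples
#' nn_intervals(c(0, 1, 2.05))  # 1000 ms, 1050 ms
#' @export
nn_intervals <- function(beats) {
  beats <- as_beat_series(beats)
  t <- beats$beat_s
  tibble(t_start_s = t[-length(t)],
         t_mid_s = (t[-length(t)] + t[-1]) / 2,
         nni_ms = diff(t) * 1000)
}

#' @rdname nn_intervals
#' @export
intervals_from_beats <- nn_intervals

#' Rebuild beat times from a sequence of NN intervals
#'
#' @param nni_ms Positive intervals in milliseconds.
#' @param t0 Time of the first beat, seconds.
#' @return A [beat_series()] whose successive differences are `nni_ms`.
#' @export
beats_from_intervals <- function(nni_ms, t0 = 0) {
  if (any(nni_ms <= 0)) abort("intervals must be positive")
  beat_series(t0 + c(0, cumsum(nni_ms) / 1000))
}

#' Remove sharp peaks from a beat series
#'
#' Pre-conditioning for spectral HRV analysis: intervals that deviate from
#' a running median of their neighbourhood by more than a fraction of that
#' median are treated as artifacts (ectopic beats, missed detections,
#' sudden rate jumps) and replaced by linear interpolation between the
#' nearest surviving intervals; beat times are then re-accumulated so the
#' total duration is preserved up to the net interval change.
#'
#' @param beats A [beat_series()].
#' @param rel_threshold Fraction of the running median beyond which an
#'   interval is flagged (0 < rel_threshold < 1).
#' @param context Width of the running-median window, in beats (odd, >= 3).
#' @return A [beat_series()] with attribute `n_replaced` giving the number
#'   of replaced intervals.
#' @examples
#' b <- beats_from_intervals(c(rep(1000, 5), 1600, rep(1000, 5)))
#' cleaned <- remove_sharp_peaks(b)
#' attr(cleaned, "n_replaced")  # 1
#' @export
remove_sharp_peaks <- function(beats, rel_threshold = 0.3, context = 11L) {
  beats <- as_beat_series(beats)
  if (rel_threshold <= 0 || rel_threshold >= 1)
    abort("`rel_threshold` must lie in (0, 1)")
  if (context < 3 || context %% 2 == 0)
    abort("`context` must be an odd integer >= 3")
  iv <- nn_intervals(beats)
  nni <- iv$nni_ms
  k <- min(context, if (length(nni) %% 2 == 0) length(nni) - 1 else length(nni))
  med <- stats::runmed(nni, k = k, endrule = "median")
  bad <- abs(nni - med) > rel_threshold * med
  if (all(bad)) abort("all intervals flagged; nothing to interpolate from")
  if (!any(bad)) {
    # untouched series returned bit-identically (idempotence)
    attr(beats, "n_replaced") <- 0L
    return(beats)
  }
  good <- which(!bad)
  nni[bad] <- approx(iv$t_mid_s[good], nni[good], xout = iv$t_mid_s[bad],
                     rule = 2)$y
  out <- beats_from_intervals(nni, t0 = beats$beat_s[1])
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Resample a beat series to a uniform tachogram
#'
#' Spectral and envelope analyses need uniform sampling, but NN intervals
#' are sampled at the (irregular) beat times.  The intervals are therefore
#' interpolated with a cubic spline against their midpoint times and
#' evaluated on a uniform grid.
#'
#' @param beats A [beat_series()].
#' @param fs_hz Sampling rate of the uniform grid in Hz; the default 4 Hz
#'   puts the Nyquist frequency (2 Hz) far above the 0.4 Hz HF band edge.
#' @return A tibble of class `tachogram` with columns `time_s`, `nni_ms`
#'   and attribute `fs_hz`; the grid spans the first to last interval
#'   midpoint.
#' @export
resample_uniform <- function(beats, fs_hz = 4) {
  beats <- as_beat_series(beats)
  if (nrow(beats) < 4) abort("need at least 4 beats to resample")
  if (fs_hz <= 2 * 0.4) abort("`fs_hz` must exceed twice the 0.4 Hz HF edge")
  iv <- nn_intervals(beats)
  span <- iv$t_mid_s[nrow(iv)] - iv$t_mid_s[1]
  if (span < 2 / 0.04)
    warn("recording spans less than 50 s; LF content will be unreliable")
  grid <- seq(iv$t_mid_s[1], iv$t_mid_s[nrow(iv)], by = 1 / fs_hz)
  vals <- spline(iv$t_mid_s, iv$nni_ms, xout = grid, method = "fmm")$y
  new_tachogram(grid, vals, fs_hz)
}

new_tachogram <- function(time_s, nni_ms, fs_hz) {
  structure(tibble(time_s = time_s, nni_ms = nni_ms),
            fs_hz = fs_hz,
            class = c("tachogram", class(tibble())))
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %g Hz, %.1f s\n",
              nrow(x), attr(x, "fs_hz"),
              x$time_s[nrow(x)] - x$time_s[1]))
  NextMethod()
}
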