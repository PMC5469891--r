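## Instantaneous amplitude: zero-phase bandpass filtering, the analytic
## signal and its envelope, and per-window two-sided trimmed means.

#' Zero-phase bandpass filter
#'
#' Band-limits a uniform tachogram with a 4th-order Butterworth bandpass
#' applied forward and backward ([signal::filtfilt()]), so the filter is
#' zero-phase -- a requirement for envelope extraction, where phase
#' distortion would corrupt the analytic signal.  The signal mean is
#' removed first.  The double pass attenuates a tone one octave outside
#' the band by more than 20 dB.
#'
#' @param tachogram A `tachogram` from [resample_uniform()].
#' @param band A [freq_band()]; its upper edge must lie below the Nyquist
#'   frequency.
#' @return A `tachogram` holding the band-limited, zero-mean signal.
#' @export
bandpass_filter <- function(tachogram, band = lf_band()) {
  stopifnot(inherits(tachogram, "tachogram"), inherits(band, "freq_band"))
  fs <- attr(tachogram, "fs_hz")
  if (band$hi >= fs / 2) abort("band upper edge must be below Nyquist")
  bf <- signal::butter(2, c(band$lo, band$hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, tachogram$nni_ms - mean(tachogram$nni_ms))
  out <- new_tachogram(tachogram$time_s, y, fs)
  attr(out, "band") <- band
  out
}

## Analytic signal via the one-sided spectrum: zero the negative
## frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) abort("empty signal")
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Hilbert envelope of a band-limited signal
#'
#' Forms the complex analytic signal of a (mean-removed, band-limited)
#' tachogram via the Hilbert transform and returns its modulus: the
#' instantaneous amplitude (iA) at every sample.  For a pure tone
#' `a*sin(2*pi*f*t)` the interior envelope equals `a`; the first and last
#' two periods of the band's lower edge suffer from FFT edge effects and
#' are marked with `edge_flag`.
#'
#' @param filtered A band-limited `tachogram`, e.g. from
#'   [bandpass_filter()] (which records its band), or any `tachogram`
#'   together with an explicit `band`.
#' @param band The [freq_band()] of the signal, used for the edge margin;
#'   taken from the filtered tachogram when available.
#' @return A tibble of class `band_envelope` with columns `time_s`,
#'   `env_ms`, `edge_flag` and attributes `band`, `fs_hz`,
#'   `edge_margin_s`.
#' @export
hilbert_envelope <- function(filtered, band = NULL) {
  stopifnot(inherits(filtered, "tachogram"))
  band <- band %||% attr(filtered, "band")
  if (is.null(band)) abort("supply `band` for a tachogram without one")
  if (nrow(filtered) == 0) abort("empty signal")
  x <- filtered$nni_ms - mean(filtered$nni_ms)
  env <- Mod(analytic_signal(x))
  margin <- 2 / band$lo
  t <- filtered$time_s
  flag <- t < t[1] + margin | t > t[length(t)] - margin
  structure(tibble(time_s = t, env_ms = env, edge_flag = flag),
            band = band, fs_hz = attr(filtered, "fs_hz"),
            edge_margin_s = margin,
            class = c("band_envelope", class(tibble())))
}

#' Two-sided trimmed mean
#'
#' Sorts the values, drops the largest and smallest ones, and averages the
#' remainder -- the robust aggregation at the heart of the
#' instantaneous-amplitude metric, which makes per-window amplitudes
#' insensitive to short large-amplitude artifacts.
#'
#' With `tail = "per_tail"` (the default reading of "the 20% largest and
#' smallest values"), `floor(trim * n)` values are dropped from *each*
#' tail; with `tail = "total"` the same total fraction is split across the
#' two tails (`floor(trim/2 * n)` each).  Sorting is stable, so ties are
#' resolved by position and the result is deterministic.
#'
#' @param values Numeric vector, non-empty.
#' @param trim Trim fraction, `0 <= trim < 0.5` (per tail).
#' @param tail `"per_tail"` or `"total"`; see Details.
#' @return The trimmed mean.  If trimming would drop everything, the
#'   plain mean is returned with a warning.
#' @examples
#' trimmed_mean(1:10, 0.2)  # mean of 3..8 = 5.5
#' @export
trimmed_mean <- function(values, trim = 0.2, tail = c("per_tail", "total")) {
  tail <- match.arg(tail)
  if (length(values) == 0) abort("`values` must be non-empty")
  if (trim < 0 || trim >= 0.5) abort("`trim` must lie in [0, 0.5)")
  n <- length(values)
  k <- if (tail == "per_tail") floor(trim * n) else floor(trim / 2 * n)
  if (2 * k >= n) {
    warn("trim would drop all values; falling back to the plain mean")
    return(mean(values))
  }
  s <- sort(values, method = "radix")  # stable
  mean(s[(k + 1):(n - k)])
}

#' Per-window trimmed-mean instantaneous amplitude
#'
#' Aggregates a band envelope over a sliding-window grid: one two-sided
#' trimmed mean per window.  For a stationary in-band tone of amplitude
#' `a` every window value is `a` (up to filter and edge effects).
#'
#' @param envelope A [hilbert_envelope()].
#' @param grid A [sliding_windows()] grid within the envelope time span.
#' @param trim Trim fraction (per tail).
#' @return A tibble with `start_s`, `end_s`, `t_center_s`, `ia_ms` and
#'   `edge_flag` (window overlaps the envelope's edge margin).
#' @export
windowed_ia <- function(envelope, grid, trim = 0.2) {
  stopifnot(inherits(envelope, "band_envelope"),
            inherits(grid, "window_grid"))
  t <- envelope$time_s
  if (min(grid$start_s) < t[1] - 1e-9 ||
      max(grid$end_s) > t[length(t)] + 1e-9)
    abort("grid extends beyond the envelope time span")
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sel <- t >= grid$start_s[i] & t < grid$end_s[i]
    if (!any(sel)) abort("empty window")
    tibble(start_s = grid$start_s[i], end_s = grid$end_s[i],
           t_center_s = (grid$start_s[i] + grid$end_s[i]) / 2,
           ia_ms = trimmed_mean(envelope$env_ms[sel], trim = trim),
           edge_flag = any(envelope$edge_flag[sel]))
  })
  dplyr::bind_rows(rows)
}
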