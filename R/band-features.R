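## Frequency bands, window grids, Welch spectra, band powers, the
## normalization identities and the univariate metric family.

#' Frequency band constructors
#'
#' Conventional HRV bands: LF `[0.04, 0.15)` Hz (sympathetic-dominated) and
#' HF `[0.15, 0.4]` Hz (parasympathetic/respiratory).  Band intervals are
#' treated as half-open at the top edge of LF so that 0.15 Hz belongs to HF
#' only and no power is double counted.
#'
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @param name Band name.
#' @return A list of class `freq_band` with elements `lo`, `hi`, `name`.
#' @export
freq_band <- function(lo, hi, name = "band") {
  if (!(lo > 0 && hi > lo)) abort("need 0 < lo < hi")
  structure(list(lo = lo, hi = hi, name = name), class = "freq_band")
}

#' @rdname freq_band
#' @export
lf_band <- function() freq_band(0.04, 0.15, "LF")

#' @rdname freq_band
#' @export
hf_band <- function() freq_band(0.15, 0.4, "HF")

#' Build a sliding-window grid
#'
#' Standard HRV practice analyzes overlapping sliding windows, typically
#' 5 min long with a 10 s increment, so that each window holds enough
#' cycles of the slowest frequency of interest.
#'
#' @param t_start_s,t_end_s Span to cover, seconds.
#' @param length_s Window length in seconds (default 300).
#' @param step_s Sliding increment in seconds (default 10).
#' @param f_lo Lowest analyzed frequency in Hz, used only to warn when
#'   windows are shorter than ten of its cycles.
#' @return A tibble of class `window_grid` with half-open windows
#'   `[start_s, end_s)` and attributes `length_s`, `step_s`.
#' @examples
#' nrow(sliding_windows(0, 600))  # 31 windows
#' @export
sliding_windows <- function(t_start_s, t_end_s, length_s = 300, step_s = 10,
                            f_lo = 0.04) {
  if (step_s <= 0) abort("`step_s` must be > 0")
  if (t_end_s - t_start_s < length_s)
    abort("span is shorter than one window")
  if (length_s < 10 / f_lo)
    warn(sprintf("windows of %g s hold fewer than 10 cycles of %g Hz",
                 length_s, f_lo))
  starts <- seq(t_start_s, t_end_s - length_s, by = step_s)
  structure(tibble(start_s = starts, end_s = starts + length_s),
            length_s = length_s, step_s = step_s,
            class = c("window_grid", class(tibble())))
}

#' Window-length validity arithmetic
#'
#' Reliable band-power estimation needs sufficiently many cycles of the
#' lowest frequency of interest per window (the LF lower edge, 0.04 Hz,
#' has a 25 s period), the minimum resolvable period is one tenth of the
#' window length, and the beat rate itself sets the Nyquist frequency of
#' the non-interpolated interval series (half the heart rate).
#'
#' @param length_s Window length in seconds.
#' @param f_lo Lowest frequency of interest, Hz.
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @return A tibble with `cycles` (complete cycles of `f_lo` per window),
#'   `min_period_s` (`length_s / 10`) and `nyquist_hz`
#'   (`heart_rate_bpm / 120`).
#' @examples
#' validate_window_length(300, 0.04, 60)  # 12 cycles, 30 s, 0.5 Hz
#' @export
validate_window_length <- function(length_s, f_lo = 0.04,
                                   heart_rate_bpm = 60) {
  stopifnot(length_s > 0, f_lo > 0, heart_rate_bpm > 0)
  tibble(cycles = floor(length_s * f_lo),
         min_period_s = length_s / 10,
         nyquist_hz = heart_rate_bpm / 120)
}

#' Welch power spectral density of a uniform tachogram
#'
#' Mean-removed, Hann-tapered, 50%-overlapping segment-averaged one-sided
#' periodogram in density scaling (ms^2/Hz): integrating the returned
#' density over frequency recovers the signal variance.  The 100 s default
#' segment keeps at least four cycles of the LF lower edge per segment.
#'
#' @param x A `tachogram` or numeric vector.
#' @param fs_hz Sampling rate, taken from the tachogram when omitted.
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @return A tibble with columns `freq_hz` and `psd_ms2_hz`.
#' @export
psd_welch <- function(x, fs_hz = NULL, segment_s = 100, overlap = 0.5) {
  if (inherits(x, "tachogram")) {
    fs_hz <- fs_hz %||% attr(x, "fs_hz")
    x <- x$nni_ms
  }
  if (is.null(fs_hz)) abort("`fs_hz` is required for plain vectors")
  if (length(x) == 0) abort("empty signal")
  n <- length(x)
  nseg <- min(n, max(8L, round(segment_s * fs_hz)))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))  # Hann
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    xf <- fft(seg)[seq_len(nf)]
    p <- Mod(xf)^2 / (fs_hz * u)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided
    acc <- acc + p
  }
  tibble(freq_hz = (seq_len(nf) - 1L) * fs_hz / nseg,
         psd_ms2_hz = acc / length(starts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Trapezoid integral of a PSD over [band$lo, band$hi).
integrate_band <- function(freq, psd, band) {
  sel <- freq >= band$lo & freq < band$hi
  if (sum(sel) < 2) return(0)
  f <- freq[sel]
  p <- psd[sel]
  sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
}

#' Band power of a uniform tachogram
#'
#' Integrates the mean-removed Welch spectral density over a frequency
#' band by the trapezoid rule.  For a pure in-band tone of amplitude `a`
#' the result is `a^2 / 2` (the tone's variance).
#'
#' @param tachogram A `tachogram` from [resample_uniform()], or a numeric
#'   vector together with `fs_hz`.
#' @param band A [freq_band()]; power is integrated over `[lo, hi)`.
#' @inheritParams psd_welch
#' @return Band power in ms^2 (non-negative scalar).
#' @export
band_power <- function(tachogram, band = lf_band(), fs_hz = NULL,
                       segment_s = 100, overlap = 0.5) {
  stopifnot(inherits(band, "freq_band"))
  spec <- psd_welch(tachogram, fs_hz = fs_hz, segment_s = segment_s,
                    overlap = overlap)
  n_cyc <- if (inherits(tachogram, "tachogram")) {
    (tachogram$time_s[nrow(tachogram)] - tachogram$time_s[1]) * band$lo
  } else NA_real_
  if (!is.na(n_cyc) && n_cyc < 10)
    warn(sprintf("signal holds only %.1f cycles of the %g Hz band edge",
                 n_cyc, band$lo))
  max(0, integrate_band(spec$freq_hz, spec$psd_ms2_hz, band))
}

#' Normalized band powers
#'
#' With total power operationalized as `LFp + HFp`, the normalized powers
#' are `LFn = LFp / (LFp + HFp)` and `HFn = HFp / (LFp + HFp)`.  They sum
#' to one exactly, i.e. `HFn = 1 - LFn`: normalization projects every
#' (LFp, HFp) pair onto a line and removes one degree of freedom.  Pairs
#' with zero total power are flagged undefined (`NA`).
#'
#' @param LFp,HFp Band powers in ms^2 (vectors recycle as usual).
#' @return A tibble with columns `LFn` and `HFn`.
#' @examples
#' normalize_powers(3, 1)  # 0.75, 0.25
#' @export
normalize_powers <- function(LFp, HFp) {
  if (any(LFp < 0 | HFp < 0, na.rm = TRUE)) abort("powers must be >= 0")
  tp <- LFp + HFp
  undef <- !is.na(tp) & tp == 0
  if (any(undef)) {
    warn("total power is zero for some rows; normalized powers set to NA")
    tp[undef] <- NA_real_
  }
  tibble(LFn = LFp / tp, HFn = HFp / tp)
}

#' Constants for the univariate metric family
#'
#' User-defined constants of the alternative sympathovagal metrics P2--P5;
#' multiplicative constants default to 1 and additive offsets to 0, and
#' multiplicative constants must be positive for the family's defining
#' monotonicity (increasing in LFp, decreasing in HFp) to hold.
#'
#' @param b1,b2 Constants of P2 (`b1 * LFp^2 / HFp + b2`).
#' @param c1,c2,c3 Constants of P3 (`c1 * LFp - c2 * HFp + c3`).
#' @param d1,d2,d3 Constants of P4 (`d1 * LFp^2 - d2 * HFp + d3`).
#' @param e1,e2 Constants of P5 (`e1 * LFp / HFp^2 + e2`).
#' @return A list of class `metric_constants`.
#' @export
metric_constants <- function(b1 = 1, b2 = 0, c1 = 1, c2 = 1, c3 = 0,
                             d1 = 1, d2 = 1, d3 = 0, e1 = 1, e2 = 0) {
  if (any(c(b1, c1, c2, d1, d2, e1) <= 0))
    abort("multiplicative constants must be > 0")
  structure(list(b1 = b1, b2 = b2, c1 = c1, c2 = c2, c3 = c3,
                 d1 = d1, d2 = d2, d3 = d3, e1 = e1, e2 = e2),
            class = "metric_constants")
}

#' The univariate sympathovagal metric family
#'
#' A family of one-dimensional stress metrics that all satisfy the
#' requirements usually placed on a sympathovagal index -- increase with
#' LF power, decrease with HF power -- yet disagree with one another:
#' \deqn{P_1 = LF_p/HF_p,\quad P_2 = b_1 LF_p^2/HF_p + b_2,\quad
#'       P_3 = c_1 LF_p - c_2 HF_p + c_3,}
#' \deqn{P_4 = d_1 LF_p^2 - d_2 HF_p + d_3,\quad
#'       P_5 = e_1 LF_p/HF_p^2 + e_2.}
#' Along any locus of constant LF/HF ratio, P1 is flat while P2--P4 grow
#' and P5 shrinks with LF power, which is the ambiguity that motivates
#' treating LF and HF as a two-dimensional quantity instead.
#'
#' @param LFp,HFp Band powers, ms^2.
#' @param which One of `"P1"` ... `"P5"`.
#' @param constants A [metric_constants()].
#' @return Numeric vector of metric values; pairs whose denominator is
#'   zero (P1, P2, P5 at `HFp = 0`) are flagged undefined (`NA`).
#' @examples
#' metric_family(10, 8, "P1")  # 1.25
#' @export
metric_family <- function(LFp, HFp, which = c("P1", "P2", "P3", "P4", "P5"),
                          constants = metric_constants()) {
  which <- match.arg(which)
  stopifnot(inherits(constants, "metric_constants"))
  k <- constants
  if (which %in% c("P1", "P2", "P5")) {
    bad <- !is.na(HFp) & HFp == 0
    if (any(bad)) {
      warn("HFp is zero for some rows; ratio-type metric set to NA")
      HFp[bad] <- NA_real_
    }
  }
  switch(which,
         P1 = LFp / HFp,
         P2 = k$b1 * LFp^2 / HFp + k$b2,
         P3 = k$c1 * LFp - k$c2 * HFp + k$c3,
         P4 = k$d1 * LFp^2 - k$d2 * HFp + k$d3,
         P5 = k$e1 * LFp / HFp^2 + k$e2)
}

## Assign each window the label of the segment that fully contains it
## after trimming `buffer_s` from both segment ends; windows straddling
## (buffered) segment boundaries get NA.
assign_window_labels <- function(grid, segments, buffer_s = 0) {
  purrr::map_chr(seq_len(nrow(grid)), function(i) {
    s <- grid$start_s[i]
    e <- grid$end_s[i]
    hit <- segments$label[s >= segments$start_s + buffer_s &
                            e <= segments$end_s - buffer_s]
    if (length(hit) == 1) hit else NA_character_
  })
}

#' Per-window LF-HF feature table
#'
#' The central extraction step: for every sliding window it computes the
#' Welch band powers (`LFp_ms2`, `HFp_ms2`), total power and normalized
#' powers, the classical power ratio, and -- when band envelopes are
#' supplied -- the trimmed-mean instantaneous amplitudes (`LFiA_ms`,
#' `HFiA_ms`) and their ratio.
#'
#' When a segment table is supplied, only windows lying fully inside one
#' (buffer-trimmed) labeled segment are kept; windows straddling segment
#' boundaries have no ground-truth state and are dropped.  Without labels
#' all windows are returned with `label = NA`.
#'
#' @param tachogram A `tachogram` from [resample_uniform()].
#' @param grid A [sliding_windows()] grid (defaults to 300 s / 10 s over
#'   the tachogram span).
#' @param env_lf,env_hf Optional band envelopes from [hilbert_envelope()],
#'   on the same time grid as `tachogram`.
#' @param segments Optional segment table (`label`, `start_s`, `end_s`).
#' @param buffer_s Seconds trimmed from each end of every segment before
#'   windows are labeled (residuals from adjacent states).
#' @param trim Trim fraction for the envelope means.
#' @param segment_s,overlap Welch settings passed to [band_power()].
#' @return A tibble with one row per retained window and columns
#'   `t_center_s`, `LFp_ms2`, `HFp_ms2`, `TP_ms2`, `LFn`, `HFn`,
#'   `ratio_p`, `LFiA_ms`, `HFiA_ms`, `ratio_iA`, `label`, `quality`.
#' @export
window_features <- function(tachogram, grid = NULL, env_lf = NULL,
                            env_hf = NULL, segments = NULL, buffer_s = 0,
                            trim = 0.2, segment_s = 100, overlap = 0.5) {
  stopifnot(inherits(tachogram, "tachogram"))
  fs <- attr(tachogram, "fs_hz")
  if (is.null(grid))
    grid <- sliding_windows(tachogram$time_s[1],
                            tachogram$time_s[nrow(tachogram)])
  check_env <- function(env) {
    if (!is.null(env) && nrow(env) != nrow(tachogram))
      abort("envelopes must share the tachogram time grid")
  }
  check_env(env_lf)
  check_env(env_hf)
  labels <- if (!is.null(segments)) {
    assign_window_labels(grid, segments, buffer_s)
  } else rep(NA_character_, nrow(grid))
  keep <- if (!is.null(segments)) !is.na(labels) else rep(TRUE, nrow(grid))
  if (!any(keep)) abort("no window fits inside a labeled segment")

  rows <- purrr::map(which(keep), function(i) {
    sel <- tachogram$time_s >= grid$start_s[i] &
      tachogram$time_s < grid$end_s[i]
    x <- tachogram$nni_ms[sel]
    lfp <- band_power(x, lf_band(), fs_hz = fs, segment_s = segment_s,
                      overlap = overlap)
    hfp <- band_power(x, hf_band(), fs_hz = fs, segment_s = segment_s,
                      overlap = overlap)
    edge <- FALSE
    ia <- function(env) {
      if (is.null(env)) return(NA_real_)
      edge <<- edge || any(env$edge_flag[sel])
      trimmed_mean(env$env_ms[sel], trim = trim)
    }
    lfia <- ia(env_lf)
    hfia <- ia(env_hf)
    tibble(t_center_s = (grid$start_s[i] + grid$end_s[i]) / 2,
           LFp_ms2 = lfp, HFp_ms2 = hfp, TP_ms2 = lfp + hfp,
           LFiA_ms = lfia, HFiA_ms = hfia,
           label = labels[i], quality = !edge)
  })
  out <- dplyr::bind_rows(rows)
  norm <- normalize_powers(out$LFp_ms2, out$HFp_ms2)
  out$LFn <- norm$LFn
  out$HFn <- norm$HFn
  out$ratio_p <- ifelse(out$HFp_ms2 > 0, out$LFp_ms2 / out$HFp_ms2, NA_real_)
  out$ratio_iA <- ifelse(!is.na(out$HFiA_ms) & out$HFiA_ms > 0,
                         out$LFiA_ms / out$HFiA_ms, NA_real_)
  dplyr::select(out, "t_center_s", "LFp_ms2", "HFp_ms2", "TP_ms2",
                "LFn", "HFn", "ratio_p", "LFiA_ms", "HFiA_ms", "ratio_iA",
                "label", "quality")
}
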