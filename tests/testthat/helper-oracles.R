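# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

withr_local_file <- function(name) file.path(tempdir(), name)

# Tachogram object from explicit samples (bypasses resampling).
make_tachogram <- function(values, fs = 4, t0 = 0) {
  hrv2d:::new_tachogram(t0 + (seq_along(values) - 1) / fs, values, fs)
}

tone <- function(amp, freq, dur, fs = 4, phase = 0) {
  t <- seq(0, dur, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# Brute-force DFT periodogram band power: full-length rectangular-window
# periodogram, mean removed, power summed over band bins.
brute_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  xf <- stats::fft(x)
  p <- Mod(xf)^2 / n^2          # two-sided power per bin
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  pw <- 2 * p                   # one-sided
  pw[1] <- p[1]
  sum(pw[half & f >= lo & f < hi])
}

# Sort-slice-average trimmed mean (per-tail counts).
trimmed_oracle <- function(x, trim = 0.2) {
  n <- length(x)
  k <- floor(trim * n)
  if (2 * k >= n) return(mean(x))
  s <- sort(x)
  mean(s[(k + 1):(n - k)])
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n, nA) assignments of the pooled ranks to group A.
ranksum_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  wobs <- sum(r[seq_len(nA)])
  combos <- utils::combn(length(pooled), nA)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nA * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(wobs - mu) - 1e-9)
}

# Direct evaluation of the sharp-peak rule on explicit neighborhoods.
peak_rule_oracle <- function(nni, rel = 0.3, context = 11) {
  n <- length(nni)
  half <- (context - 1) / 2
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    med <- stats::median(nni[lo:hi])
    flagged[i] <- abs(nni[i] - med) > rel * med
  }
  flagged
}
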