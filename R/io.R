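## Plain-text interchange: RR interval files, segment label tables, and
## the per-window feature CSV.

#' Read an RR/NN interval file
#'
#' Two dialects are supported: plain RR text (one interval in milliseconds
#' per line; beat times accumulate from t = 0) and a two-column CSV with
#' header `time_s,nni_ms`, where the beat times are taken verbatim and
#' each interval closes at the next line's time.  Malformed lines are
#' reported with their line number.
#'
#' @param path Path to the file.
#' @return A [beat_series()].
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty file: %s", path))
  if (grepl("^\\s*time_s\\s*,\\s*nni_ms\\s*$", lines[1])) {
    body <- lines[-1]
    parts <- strsplit(body, ",", fixed = TRUE)
    for (i in seq_along(parts))
      if (length(parts[[i]]) != 2 ||
          anyNA(suppressWarnings(as.numeric(parts[[i]]))))
        abort(sprintf("malformed CSV line %d: '%s'", i + 1L, body[i]))
    times <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    nni <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    # each row is one interval (onset, length); the last interval's end
    # is the final beat
    return(beat_series(c(times, times[length(times)] +
                           nni[length(nni)] / 1000)))
  }
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad))
    abort(sprintf("non-numeric value on line %d: '%s'", bad[1], lines[bad[1]]))
  nonpos <- which(vals <= 0)
  if (length(nonpos))
    abort(sprintf("non-positive interval on line %d", nonpos[1]))
  beats_from_intervals(vals, t0 = 0)
}

#' Write a beat series as RR text
#'
#' One interval in milliseconds per line, `.` decimal separator,
#' newline-terminated.
#'
#' @param beats A [beat_series()].
#' @param path Output path.
#' @param digits Significant digits to keep.
#' @return `path`, invisibly.
#' @export
write_rr <- function(beats, path, digits = 10) {
  beats <- as_beat_series(beats)
  nni <- nn_intervals(beats)$nni_ms
  writeLines(format(nni, digits = digits, scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' @rdname write_rr
#' @export
write_rr_csv <- function(beats, path, digits = 10) {
  beats <- as_beat_series(beats)
  iv <- nn_intervals(beats)
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  # one row per interval: onset time and length; readers recover the final
  # beat from the last interval's end
  writeLines(c("time_s,nni_ms",
               paste(fmt(iv$t_start_s), fmt(iv$nni_ms), sep = ",")), path)
  invisible(path)
}

#' Read a segment label table
#'
#' CSV with header `label,start_s,end_s`; segments must be in increasing
#' order and non-overlapping (gaps of unlabeled time are allowed).
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `label`, `start_s`, `end_s`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("label", "start_s", "end_s")))
    abort("label file must have header `label,start_s,end_s`")
  if (nrow(df) == 0) abort("label file has no rows")
  validate_segments(as_tibble(df))
}

validate_segments <- function(segments) {
  if (any(segments$end_s <= segments$start_s))
    abort("segment end must exceed its start")
  if (nrow(segments) > 1) {
    o <- order(segments$start_s)
    segments <- segments[o, ]
    if (any(segments$start_s[-1] < segments$end_s[-nrow(segments)]))
      abort("segments overlap")
  }
  segments
}

#' @rdname read_labels
#' @param segments A segment tibble to write.
#' @export
write_labels <- function(segments, path) {
  validate_segments(as_tibble(segments))
  utils::write.csv(segments[c("label", "start_s", "end_s")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

feature_csv_cols <- c("t_center_s", "LFp_ms2", "HFp_ms2", "TP_ms2", "LFn",
                      "HFn", "ratio_p", "LFiA_ms", "HFiA_ms", "ratio_iA",
                      "label")

#' Read or write a per-window feature table
#'
#' The shared CSV surface of the feature extraction: columns
#' `t_center_s,LFp_ms2,HFp_ms2,TP_ms2,LFn,HFn,ratio_p,LFiA_ms,HFiA_ms,ratio_iA,label`.
#'
#' @param features A feature tibble from [window_features()].
#' @param path CSV path.
#' @return `read_features` returns a tibble; `write_features` returns
#'   `path` invisibly.
#' @export
write_features <- function(features, path) {
  missing_cols <- setdiff(feature_csv_cols, names(features))
  if (length(missing_cols))
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  utils::write.csv(features[feature_csv_cols], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), feature_csv_cols))
    abort("not a feature table CSV")
  as_tibble(df)
}
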