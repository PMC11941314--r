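# Beat-level and frequency-table input/output.
#
# Two input tiers: raw beat CSVs (time plus either RR interval in ms or an
# instantaneous heart rate in bpm) and precomputed frequency-repetition tables
# (heart-rate value, repetition count) -- the form in which prototype profiles
# are published.

#' Convert an RR interval to an instantaneous heart rate
#'
#' Instantaneous heart rate is defined as `60000 / RR(ms)`, rounded half-up to
#' an integer number of beats per minute.  Vectorized.
#'
#' @param rr_ms RR interval(s) in milliseconds; must be positive and finite.
#' @return Integer heart rate(s) in beats per minute.
#' @examples
#' rr_to_hr(1000) # 60
#' rr_to_hr(800)  # 75
#' @export
rr_to_hr <- function(rr_ms) {
  if (!is.numeric(rr_ms) || length(rr_ms) == 0L) {
    abort_domain("rr_ms must be a non-empty numeric vector")
  }
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    abort_domain("rr_ms must be positive and finite")
  }
  # round half-up, not R's default half-to-even
  as.integer(floor(60000 / rr_ms + 0.5))
}

#' Construct a beat series
#'
#' A beat series is the ordered sequence of beat-level heart-rate observations
#' of one recording.  Time must be strictly increasing; heart rates must be
#' positive.  Heart rates are typically whole bpm, but sub-integer resolution
#' (e.g. half-bpm steps, as produced by the synthetic generator) is accepted:
#' repetition counting distinguishes distinct stored values.
#'
#' @param recording_id Identifier for the recording.
#' @param time_s Elapsed seconds from recording start, strictly increasing.
#' @param hr_bpm Instantaneous heart rates, positive (bpm).
#' @return An object of class `beat_series` with fields `recording_id`,
#'   `beats` (data frame `time_s`, `hr_bpm`) and `duration_h`.
#' @export
beat_series <- function(recording_id, time_s, hr_bpm) {
  if (length(time_s) == 0L) {
    abort_empty("beat series must contain at least one beat")
  }
  if (length(time_s) != length(hr_bpm)) {
    abort_validation("time_s and hr_bpm must have equal length")
  }
  if (!is.numeric(time_s) || any(!is.finite(time_s)) || any(time_s < 0)) {
    abort_validation("time_s must be non-negative finite numbers")
  }
  if (!is.numeric(hr_bpm) || any(!is.finite(hr_bpm)) || any(hr_bpm < 1)) {
    abort_validation("hr_bpm must be finite and >= 1")
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "time_s must be strictly increasing; first violation at row %d",
      bad[1L] + 1L
    ))
  }
  structure(
    list(
      recording_id = as.character(recording_id)[1L],
      beats = data.frame(time_s = as.numeric(time_s),
                         hr_bpm = as.numeric(hr_bpm)),
      duration_h = (time_s[length(time_s)] - time_s[1L]) / 3600
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s: %d beats over %.3f h\n",
              x$recording_id, nrow(x$beats), x$duration_h))
  invisible(x)
}

#' Read a beat-level CSV
#'
#' Expects a header `time_s,hr_bpm` or `time_s,rr_ms` depending on
#' `column_mode`.  In `rr_ms` mode each RR interval is converted via
#' [rr_to_hr()].
#'
#' @param path Path to the CSV file.
#' @param column_mode Either `"hr_bpm"` or `"rr_ms"`.
#' @param recording_id Identifier; defaults to the file name without extension.
#' @param strict_duration If `TRUE`, require the series to span at least 21 h
#'   (the conventional minimum Holter duration).  Off by default so that short
#'   synthetic fixtures can flow through the pipeline.
#' @return A [beat_series()].
#' @export
read_beat_csv <- function(path, column_mode = c("hr_bpm", "rr_ms"),
                          recording_id = NULL, strict_duration = FALSE) {
  column_mode <- match.arg(column_mode)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    abort_format(sprintf("duplicate columns in %s: %s", path,
                         paste(nm[duplicated(nm)], collapse = ", ")))
  }
  value_col <- column_mode
  if (!all(c("time_s", value_col) %in% nm)) {
    abort_format(sprintf("expected columns time_s,%s in %s", value_col, path))
  }
  if (nrow(raw) == 0L) abort_empty(sprintf("no beats in %s", path))
  hr <- if (column_mode == "rr_ms") rr_to_hr(raw$rr_ms) else raw$hr_bpm
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  series <- beat_series(recording_id, raw$time_s, hr)
  if (strict_duration && series$duration_h < 21) {
    abort_validation(sprintf(
      "recording %s spans %.2f h; at least 21 h required in strict mode",
      recording_id, series$duration_h
    ))
  }
  series
}

#' Write a beat series to CSV
#'
#' Emits the `time_s,hr_bpm` dialect accepted by [read_beat_csv()].
#'
#' @param series A [beat_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  df <- series$beats
  # %.10g keeps half-bpm values exact in text form
  out <- data.frame(time_s = sprintf("%.10g", df$time_s),
                    hr_bpm = sprintf("%.10g", df$hr_bpm))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a frequency-repetition table
#'
#' One row per heart-rate value with its whole-recording repetition count.
#' Values must be unique; counts must be non-negative integers.
#'
#' @param hr_bpm Heart-rate values (bpm), unique, positive.
#' @param count Non-negative integer repetition counts.
#' @return A data frame of class `frequency_table` with columns `hr_bpm`,
#'   `count`.
#' @export
frequency_table <- function(hr_bpm = numeric(), count = integer()) {
  if (length(hr_bpm) != length(count)) {
    abort_validation("hr_bpm and count must have equal length")
  }
  if (length(hr_bpm) > 0L) {
    if (!is.numeric(hr_bpm) || any(!is.finite(hr_bpm)) || any(hr_bpm < 1)) {
      abort_validation("hr_bpm must be finite and >= 1")
    }
    if (anyDuplicated(hr_bpm)) {
      abort_validation(sprintf(
        "duplicate hr_bpm values: %s",
        paste(unique(hr_bpm[duplicated(hr_bpm)]), collapse = ", ")
      ))
    }
    if (!all(is_wholeish(count)) || any(count < 0)) {
      abort_validation("count must be non-negative integers")
    }
  }
  structure(
    data.frame(hr_bpm = as.numeric(hr_bpm), count = as.integer(round(count))),
    class = c("frequency_table", "data.frame")
  )
}

#' Read a frequency-repetition table from CSV
#'
#' Expects a header `hr_bpm,count`.  An empty body yields an empty table.
#'
#' @param path Path to the CSV file.
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("hr_bpm", "count") %in% names(raw))) {
    abort_format(sprintf("expected columns hr_bpm,count in %s", path))
  }
  frequency_table(raw$hr_bpm, raw$count)
}

#' Write a frequency-repetition table to CSV
#'
#' @param table A [frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  out <- data.frame(hr_bpm = sprintf("%.10g", table$hr_bpm),
                    count = table$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
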