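# Repetition profiles: per-heart-rate-value repetition counts with 5-bpm
# group labels.  A repetition is the number of times a specific heart-rate
# value recurs during the whole recording; values are then grouped into
# 5-beat-per-minute ranges labelled by the nearest multiple of 5.

#' 5-bpm group label of a heart-rate value
#'
#' Returns the multiple of 5 nearest to `hr_bpm`.  Exact midpoints (x.5
#' fractions landing halfway between two multiples) round up; they cannot
#' occur for whole-bpm or half-bpm inputs away from `label +/- 2.5`.
#'
#' @param hr_bpm Positive heart-rate value(s) in bpm.
#' @return Integer multiple(s) of 5.
#' @examples
#' label_of(57) # 55
#' label_of(58) # 60
#' @export
label_of <- function(hr_bpm) {
  if (!is.numeric(hr_bpm) || length(hr_bpm) == 0L) {
    abort_domain("hr_bpm must be a non-empty numeric vector")
  }
  if (any(!is.finite(hr_bpm)) || any(hr_bpm < 1)) {
    abort_domain("hr_bpm must be finite and >= 1")
  }
  as.integer(5 * floor(hr_bpm / 5 + 0.5))
}

new_repetition_profile <- function(recording_id, hr_bpm, count) {
  if (length(hr_bpm) > 0L) {
    # deterministic report order: descending count, ties by descending hr
    o <- order(-count, -hr_bpm)
    hr_bpm <- hr_bpm[o]
    count <- count[o]
    entries <- data.frame(
      hr_bpm = as.numeric(hr_bpm),
      label_bpm = label_of(hr_bpm),
      count = as.integer(count)
    )
  } else {
    entries <- data.frame(hr_bpm = numeric(), label_bpm = integer(),
                          count = integer())
  }
  structure(
    list(
      recording_id = as.character(recording_id)[1L],
      entries = entries,
      total_beats = as.integer(sum(count))
    ),
    class = "repetition_profile"
  )
}

#' Build the repetition profile of a beat series
#'
#' Counts, for each distinct heart-rate value present, how many beats carry
#' that value over the whole recording, and attaches the 5-bpm group label of
#' each value.  Entries are sorted by descending count, ties broken by
#' descending heart rate.
#'
#' @param series A [beat_series()].
#' @return An object of class `repetition_profile` with fields
#'   `recording_id`, `entries` (data frame `hr_bpm`, `label_bpm`, `count`)
#'   and `total_beats`.
#' @export
build_profile <- function(series) {
  if (!inherits(series, "beat_series")) {
    abort_validation("series must be a beat_series")
  }
  if (nrow(series$beats) == 0L) abort_empty("cannot profile an empty series")
  counts <- table(series$beats$hr_bpm)
  new_repetition_profile(series$recording_id,
                         as.numeric(names(counts)),
                         as.integer(counts))
}

#' Build a repetition profile from a frequency-repetition table
#'
#' Mirrors the table rows as profile entries, assigning 5-bpm labels with
#' [label_of()]; `total_beats` is the sum of counts.
#'
#' @param table A [frequency_table()].
#' @param recording_id Identifier attached to the profile.
#' @return A `repetition_profile`.
#' @export
profile_from_table <- function(table, recording_id = "table") {
  if (!inherits(table, "frequency_table")) {
    abort_validation("table must be a frequency_table")
  }
  new_repetition_profile(recording_id, table$hr_bpm, table$count)
}

#' @export
print.repetition_profile <- function(x, ...) {
  cat(sprintf("<repetition_profile> %s: %d distinct heart-rate values, %d beats\n",
              x$recording_id, nrow(x$entries), x$total_beats))
  if (nrow(x$entries) > 0L) {
    print(utils::head(x$entries, 10L), row.names = FALSE)
    if (nrow(x$entries) > 10L) cat(sprintf("... %d more rows\n",
                                           nrow(x$entries) - 10L))
  }
  invisible(x)
}

#' Write a repetition profile to disk
#'
#' Emits a CSV (`hr_bpm,label_bpm,count`) and, optionally, a JSON report
#' carrying `recording_id` and `total_beats` alongside the entries.
#'
#' @param profile A `repetition_profile`.
#' @param csv_path Output CSV path.
#' @param json_path Optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_profile <- function(profile, csv_path, json_path = NULL) {
  stopifnot(inherits(profile, "repetition_profile"))
  e <- profile$entries
  out <- data.frame(hr_bpm = sprintf("%.10g", e$hr_bpm),
                    label_bpm = e$label_bpm, count = e$count)
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(recording_id = profile$recording_id,
           total_beats = profile$total_beats,
           entries = e),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
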