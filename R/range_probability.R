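# Core computation: repetition-range filtering, within-range probability
# distributions over 5-bpm labels, and the summed-top-probabilities statistic.
#
# A qualifying pair is a (heart-rate value, repetition count) profile entry
# whose count falls inside an inclusive repetition range.  Within a range each
# qualifying pair is equally probable, so the probability of a 5-bpm label is
# its number of qualifying pairs divided by the range total.  The per-range
# statistic is the sum of the two largest label probabilities ("sum of the
# most frequent probabilities").

#' Construct a repetition range
#'
#' @param name Short identifier, e.g. `"P1"`.
#' @param lo,hi Inclusive repetition-count bounds, `0 < lo <= hi`.
#' @return An object of class `repetition_range`.
#' @export
repetition_range <- function(name, lo, hi) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("range name must be a non-empty string")
  }
  if (!is_wholeish(lo) || !is_wholeish(hi) || lo <= 0 || lo > hi) {
    abort_validation(sprintf("invalid repetition range [%s, %s]: need 0 < lo <= hi",
                             lo, hi))
  }
  structure(list(name = name, lo = as.integer(lo), hi = as.integer(hi)),
            class = "repetition_range")
}

#' Default repetition ranges
#'
#' The two standard ranges: P1 = 1000--2000 and P2 = 2001--3000 repetitions,
#' inclusive on both ends so they partition 1000--3000.
#'
#' @return A named list of two [repetition_range()] objects.
#' @export
default_ranges <- function() {
  list(P1 = repetition_range("P1", 1000, 2000),
       P2 = repetition_range("P2", 2001, 3000))
}

#' @export
print.repetition_range <- function(x, ...) {
  cat(sprintf("<repetition_range> %s: [%d, %d]\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Qualifying pairs of a profile within a repetition range
#'
#' @param profile A `repetition_profile`.
#' @param range A [repetition_range()].
#' @return Data frame with columns `label_bpm`, `hr_bpm`, `count`, in the
#'   profile's deterministic order; zero rows when nothing qualifies.
#' @export
filter_range <- function(profile, range) {
  stopifnot(inherits(profile, "repetition_profile"),
            inherits(range, "repetition_range"))
  e <- profile$entries
  keep <- e$count >= range$lo & e$count <= range$hi
  out <- e[keep, c("label_bpm", "hr_bpm", "count")]
  rownames(out) <- NULL
  out
}

# sum of the two largest probabilities (ties: the two largest values of the
# descending sort); the single probability when only one label qualifies
top_two_sum <- function(probs) {
  if (length(probs) == 0L) return(0)
  s <- sort(unname(probs), decreasing = TRUE)
  sum(s[seq_len(min(2L, length(s)))])
}

#' Within-range probability distribution over 5-bpm labels
#'
#' Each qualifying pair carries probability `1 / n_pairs`; a label's
#' probability is therefore its number of qualifying pairs over the total.
#' Probabilities are kept at full precision -- rounding is presentation only.
#'
#' @param qualifying Data frame of qualifying pairs as returned by
#'   [filter_range()].
#' @param range The [repetition_range()] the pairs were filtered with.
#' @return An object of class `range_distribution` with fields `range`,
#'   `qualifying`, `n_pairs`, `label_probs` (named numeric, ascending label),
#'   `top_sum`, `freq_min`, `freq_max` (NA when empty), and `peak_labels`.
#' @export
range_distribution <- function(qualifying, range) {
  stopifnot(inherits(range, "repetition_range"))
  if (!is.data.frame(qualifying) ||
      !all(c("label_bpm", "count") %in% names(qualifying))) {
    abort_validation("qualifying must be a data frame with label_bpm and count")
  }
  if (nrow(qualifying) > 0L &&
      (any(qualifying$count < range$lo) || any(qualifying$count > range$hi))) {
    abort_validation("qualifying pairs must satisfy the range bounds")
  }
  n <- nrow(qualifying)
  if (n == 0L) {
    probs <- stats::setNames(numeric(), character())
    peak <- integer()
    fmin <- fmax <- NA_integer_
    ts <- 0
  } else {
    tab <- table(qualifying$label_bpm)
    labels <- as.integer(names(tab))
    o <- order(labels)
    probs <- stats::setNames(as.numeric(tab)[o] / n, labels[o])
    mx <- max(probs)
    peak <- as.integer(names(probs)[probs >= mx - 1e-12])
    fmin <- min(labels)
    fmax <- max(labels)
    ts <- top_two_sum(probs)
  }
  structure(
    list(range = range, qualifying = qualifying, n_pairs = n,
         label_probs = probs, top_sum = ts,
         freq_min = fmin, freq_max = fmax, peak_labels = peak),
    class = "range_distribution"
  )
}

#' Summed top probabilities of a range distribution
#'
#' The sum of the two largest per-label probabilities: equal to the single
#' probability when only one label qualifies, and 0 for an empty range.
#'
#' With `digits` set, each label probability is first rounded to that many
#' decimals and the two largest rounded values are summed.  This reproduces
#' the arithmetic of published summary tables, which sum the displayed
#' two-decimal probabilities (e.g. 0.27 + 0.27 = 0.54 where full precision
#' gives 6/11 = 0.5455).  Classification always uses full precision.
#'
#' @param dist A [range_distribution()].
#' @param digits Optional number of decimals to round per-label probabilities
#'   to before summing; `NULL` (default) keeps full precision.
#' @return A probability in `[0, 1]`.
#' @export
top_sum <- function(dist, digits = NULL) {
  stopifnot(inherits(dist, "range_distribution"))
  if (is.null(digits)) return(dist$top_sum)
  top_two_sum(round(dist$label_probs, digits))
}

#' @export
print.range_distribution <- function(x, ...) {
  cat(sprintf("<range_distribution> %s [%d, %d]: %d qualifying pairs, top_sum %.4g\n",
              x$range$name, x$range$lo, x$range$hi, x$n_pairs, x$top_sum))
  if (x$n_pairs > 0L) {
    print(round(x$label_probs, 4))
  }
  invisible(x)
}

#' Per-range dynamics features of a repetition profile
#'
#' Runs [filter_range()] and [range_distribution()] for each configured range
#' and assembles, per range: the number of qualifying pairs, the summed top
#' probabilities, the qualifying-label bounds, the largest single label
#' probability, and the peak labels.
#'
#' @param profile A `repetition_profile`.
#' @param ranges Named list of non-overlapping [repetition_range()] objects;
#'   defaults to [default_ranges()].
#' @return An object of class `dynamics_features`: a data frame with one row
#'   per range (`range`, `lo`, `hi`, `n_pairs`, `top_sum`, `freq_min`,
#'   `freq_max`, `max_prob`, `single_pair`) carrying the full distributions in
#'   attribute `"distributions"`.
#' @export
extract_features <- function(profile, ranges = default_ranges()) {
  stopifnot(inherits(profile, "repetition_profile"))
  if (length(ranges) == 0L) abort_config("at least one range is required")
  for (r in ranges) stopifnot(inherits(r, "repetition_range"))
  nm <- vapply(ranges, `[[`, "", "name")
  if (anyDuplicated(nm)) abort_config("range names must be unique")
  # pairwise overlap check on inclusive integer bounds
  if (length(ranges) > 1L) {
    for (i in seq_along(ranges)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (ranges[[i]]$lo <= ranges[[j]]$hi && ranges[[j]]$lo <= ranges[[i]]$hi) {
          abort_config(sprintf("ranges %s and %s overlap", nm[j], nm[i]))
        }
      }
    }
  }
  dists <- lapply(ranges, function(r) {
    range_distribution(filter_range(profile, r), r)
  })
  names(dists) <- nm
  rows <- data.frame(
    range = nm,
    lo = vapply(ranges, function(r) r$lo, 1L),
    hi = vapply(ranges, function(r) r$hi, 1L),
    n_pairs = vapply(dists, function(d) d$n_pairs, 1L),
    top_sum = vapply(dists, function(d) d$top_sum, 1),
    freq_min = vapply(dists, function(d) as.integer(d$freq_min), 1L),
    freq_max = vapply(dists, function(d) as.integer(d$freq_max), 1L),
    max_prob = vapply(dists, function(d) {
      if (d$n_pairs == 0L) 0 else max(d$label_probs)
    }, 1),
    single_pair = vapply(dists, function(d) d$n_pairs == 1L, TRUE),
    row.names = NULL
  )
  structure(rows,
            class = c("dynamics_features", "data.frame"),
            recording_id = profile$recording_id,
            distributions = dists)
}

#' @export
print.dynamics_features <- function(x, ...) {
  cat(sprintf("<dynamics_features> %s\n", attr(x, "recording_id")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a per-recording range report
#'
#' JSON report with, per range, the qualifying pairs, label probabilities,
#' summed top probabilities and frequency bounds; optionally a flat CSV with
#' one row per (range, label) probability.
#'
#' @param features A [extract_features()] result.
#' @param json_path Output JSON path.
#' @param csv_path Optional flat CSV path.
#' @return `json_path`, invisibly.
#' @export
write_range_report <- function(features, json_path, csv_path = NULL) {
  stopifnot(inherits(features, "dynamics_features"))
  dists <- attr(features, "distributions")
  per_range <- lapply(dists, function(d) {
    list(lo = d$range$lo, hi = d$range$hi, n_pairs = d$n_pairs,
         qualifying = d$qualifying,
         label_probs = as.list(d$label_probs),
         top_sum = d$top_sum,
         freq_min = if (is.na(d$freq_min)) NULL else d$freq_min,
         freq_max = if (is.na(d$freq_max)) NULL else d$freq_max,
         peak_labels = d$peak_labels)
  })
  jsonlite::write_json(
    list(recording_id = attr(features, "recording_id"), ranges = per_range),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(csv_path)) {
    flat <- do.call(rbind, lapply(names(dists), function(nm) {
      d <- dists[[nm]]
      if (d$n_pairs == 0L) return(NULL)
      data.frame(range = nm, label_bpm = as.integer(names(d$label_probs)),
                 n_pairs_label = as.integer(round(d$label_probs * d$n_pairs)),
                 prob = as.numeric(d$label_probs))
    }))
    if (is.null(flat)) {
      flat <- data.frame(range = character(), label_bpm = integer(),
                         n_pairs_label = integer(), prob = numeric())
    }
    utils::write.csv(flat, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
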