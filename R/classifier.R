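# Band-based classification of cardiac dynamics.
#
# Each dynamics class (normal, chronic, acute, pacemaker) is characterized by
# inclusive bands on the per-range features: number of qualifying pairs,
# summed top probabilities, and the heart-rate labels where qualifying pairs
# occur.  A supplementary rule separates normal from loaded dynamics by the
# largest single label probability (< 0.3 for normal, >= 0.3 somewhere for the
# others), applied only to ranges holding at least two qualifying pairs so
# that a structurally trivial single-pair probability of 1 is never mistaken
# for a loaded peak.
#
# The combination rule is deliberately conservative: a recording is assigned
# to a class only when every predicate of exactly one class passes; otherwise
# it is reported as unclassified with a full audit trail.

DYNAMICS_CLASSES <- c("normal", "chronic", "acute", "pacemaker")

# interval membership with a small tolerance on the closed endpoints so that
# probabilities assembled from rationals (e.g. 0.3 + 0.3) compare sanely
in_band <- function(x, band, eps = 1e-9) {
  x >= band[1L] - eps & x <= band[2L] + eps
}

#' Default classification bands
#'
#' The reference bands for the four dynamics classes, per repetition range:
#' \describe{
#'   \item{qualifying pairs, P1 (1000--2000)}{normal 11--14, chronic 21--31,
#'     acute 9--11, pacemaker 4--5}
#'   \item{qualifying pairs, P2 (2001--3000)}{normal 0--3, chronic 10--14,
#'     acute 3--6, pacemaker 2}
#'   \item{summed top probabilities, P1}{normal 0.35--0.46, chronic
#'     0.35--0.48, acute 0.5--0.6, pacemaker 0.5--0.6}
#'   \item{summed top probabilities, P2}{normal 0--1, chronic 0.54--0.7,
#'     acute 0.46--0.75, pacemaker 1}
#'   \item{qualifying-label interval (bpm)}{normal 55--95, chronic 65--105,
#'     acute 75--100, pacemaker 60--75}
#' }
#' The max-single-probability rule is `"all_below"` (each range with >= 2
#' qualifying pairs peaks below 0.3) for normal and `"any_at_or_above"`
#' (some such range peaks at or above 0.3) for the other classes.
#'
#' @return An object of class `class_bands`: a named list with one entry per
#'   class, each holding `ranges` (per-range `n_pairs` and `top_sum` bands),
#'   `freq_bpm`, and `max_prob_rule`.
#' @export
default_bands <- function() {
  bands <- list(
    normal = list(
      ranges = list(
        P1 = list(n_pairs = c(11, 14), top_sum = c(0.35, 0.46)),
        P2 = list(n_pairs = c(0, 3), top_sum = c(0, 1))
      ),
      freq_bpm = c(55, 95),
      max_prob_rule = list(type = "all_below", threshold = 0.3)
    ),
    chronic = list(
      ranges = list(
        P1 = list(n_pairs = c(21, 31), top_sum = c(0.35, 0.48)),
        P2 = list(n_pairs = c(10, 14), top_sum = c(0.54, 0.7))
      ),
      freq_bpm = c(65, 105),
      max_prob_rule = list(type = "any_at_or_above", threshold = 0.3)
    ),
    acute = list(
      ranges = list(
        P1 = list(n_pairs = c(9, 11), top_sum = c(0.5, 0.6)),
        P2 = list(n_pairs = c(3, 6), top_sum = c(0.46, 0.75))
      ),
      freq_bpm = c(75, 100),
      max_prob_rule = list(type = "any_at_or_above", threshold = 0.3)
    ),
    pacemaker = list(
      ranges = list(
        P1 = list(n_pairs = c(4, 5), top_sum = c(0.5, 0.6)),
        P2 = list(n_pairs = c(2, 2), top_sum = c(1, 1))
      ),
      freq_bpm = c(60, 75),
      max_prob_rule = list(type = "any_at_or_above", threshold = 0.3)
    )
  )
  structure(bands, class = "class_bands")
}

validate_bands <- function(bands) {
  if (!is.list(bands) || length(bands) == 0L) {
    abort_config("bands must be a non-empty list of class definitions")
  }
  for (cls in names(bands)) {
    b <- bands[[cls]]
    if (!all(c("ranges", "freq_bpm", "max_prob_rule") %in% names(b))) {
      abort_config(sprintf("class %s: need ranges, freq_bpm, max_prob_rule", cls))
    }
    for (rn in names(b$ranges)) {
      for (field in c("n_pairs", "top_sum")) {
        iv <- b$ranges[[rn]][[field]]
        if (length(iv) != 2L || iv[1L] > iv[2L]) {
          abort_config(sprintf("class %s, range %s: invalid %s interval",
                               cls, rn, field))
        }
      }
    }
    if (length(b$freq_bpm) != 2L || b$freq_bpm[1L] > b$freq_bpm[2L]) {
      abort_config(sprintf("class %s: invalid freq_bpm interval", cls))
    }
    if (!b$max_prob_rule$type %in% c("all_below", "any_at_or_above", "none")) {
      abort_config(sprintf("class %s: unknown max_prob_rule type %s",
                           cls, b$max_prob_rule$type))
    }
  }
  structure(bands, class = "class_bands")
}

#' Read classification bands from a JSON configuration file
#'
#' The file mirrors the structure of [default_bands()], so users can
#' recalibrate bands on their own cohorts without touching code.
#'
#' @param path Path to a JSON band file, as written by [write_bands()].
#' @return A `class_bands` object.
#' @export
read_bands <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (cls in names(raw)) {
    raw[[cls]]$freq_bpm <- as.numeric(raw[[cls]]$freq_bpm)
    for (rn in names(raw[[cls]]$ranges)) {
      raw[[cls]]$ranges[[rn]] <- lapply(raw[[cls]]$ranges[[rn]], as.numeric)
    }
  }
  validate_bands(raw)
}

#' Write classification bands to a JSON configuration file
#'
#' @param bands A `class_bands` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bands <- function(bands, path) {
  validate_bands(bands)
  jsonlite::write_json(unclass(bands), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Classify a recording's dynamics features
#'
#' Evaluates every predicate of every class against the per-range features and
#' returns the unique class whose predicates all pass; if none or several
#' classes pass in full, the recording is `"unclassified"`.  The returned
#' audit trail records a verdict for every predicate of every class.
#'
#' @param features A [extract_features()] result.
#' @param bands A `class_bands` object; defaults to [default_bands()].  Its
#'   range names must match those of `features`.
#' @return An object of class `diagnosis`: list with `predicted`,
#'   `passed_classes`, and `audit` (data frame `class`, `range`, `predicate`,
#'   `observed`, `lo`, `hi`, `passed`).
#' @export
classify <- function(features, bands = default_bands()) {
  stopifnot(inherits(features, "dynamics_features"))
  bands <- validate_bands(bands)
  feat_ranges <- features$range
  audit <- list()
  passed_classes <- character()
  for (cls in names(bands)) {
    b <- bands[[cls]]
    if (!setequal(names(b$ranges), feat_ranges)) {
      abort_config(sprintf(
        "class %s bands reference ranges {%s} but features carry {%s}",
        cls, paste(names(b$ranges), collapse = ","),
        paste(feat_ranges, collapse = ",")
      ))
    }
    cls_pass <- TRUE
    for (rn in feat_ranges) {
      f <- features[features$range == rn, ]
      rb <- b$ranges[[rn]]
      checks <- list(
        n_pairs = c(f$n_pairs, rb$n_pairs),
        top_sum = c(f$top_sum, rb$top_sum)
      )
      for (pred in names(checks)) {
        v <- checks[[pred]]
        ok <- in_band(v[1L], v[2:3])
        audit[[length(audit) + 1L]] <- data.frame(
          class = cls, range = rn, predicate = pred,
          observed = v[1L], lo = v[2L], hi = v[3L], passed = ok
        )
        cls_pass <- cls_pass && ok
      }
      # qualifying labels must sit inside the class frequency interval;
      # vacuously true when the range is empty
      ok_freq <- f$n_pairs == 0L ||
        (f$freq_min >= b$freq_bpm[1L] && f$freq_max <= b$freq_bpm[2L])
      audit[[length(audit) + 1L]] <- data.frame(
        class = cls, range = rn, predicate = "freq_labels",
        observed = if (f$n_pairs == 0L) NA_real_ else f$freq_min,
        lo = b$freq_bpm[1L], hi = b$freq_bpm[2L], passed = ok_freq
      )
      cls_pass <- cls_pass && ok_freq
    }
    # max-single-probability rule over ranges with >= 2 qualifying pairs
    rule <- b$max_prob_rule
    eligible <- features$n_pairs >= 2L
    ok_rule <- switch(
      rule$type,
      none = TRUE,
      all_below = all(features$max_prob[eligible] < rule$threshold + 1e-9),
      any_at_or_above = !any(eligible) ||
        any(features$max_prob[eligible] >= rule$threshold - 1e-9)
    )
    audit[[length(audit) + 1L]] <- data.frame(
      class = cls, range = "*", predicate = paste0("max_prob_", rule$type),
      observed = if (any(eligible)) max(features$max_prob[eligible]) else NA_real_,
      lo = NA_real_, hi = rule$threshold, passed = ok_rule
    )
    cls_pass <- cls_pass && ok_rule
    if (cls_pass) passed_classes <- c(passed_classes, cls)
  }
  predicted <- if (length(passed_classes) == 1L) passed_classes else "unclassified"
  structure(
    list(predicted = predicted,
         passed_classes = passed_classes,
         audit = do.call(rbind, audit)),
    class = "diagnosis"
  )
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis> predicted: %s\n", x$predicted))
  if (length(x$passed_classes) > 1L) {
    cat("  (ambiguous: ", paste(x$passed_classes, collapse = ", "), ")\n", sep = "")
  }
  fails <- x$audit[!x$audit$passed, ]
  cat(sprintf("  predicates evaluated: %d, failed: %d\n",
              nrow(x$audit), nrow(fails)))
  invisible(x)
}

#' Write a diagnosis report to JSON
#'
#' @param diagnosis A [classify()] result.
#' @param features The features the diagnosis was computed from.
#' @param path Output JSON path.
#' @param meta Optional named list embedded under `"meta"` (seed, config hash).
#' @return `path`, invisibly.
#' @export
write_diagnosis <- function(diagnosis, features, path, meta = NULL) {
  stopifnot(inherits(diagnosis, "diagnosis"))
  jsonlite::write_json(
    list(recording_id = attr(features, "recording_id"),
         predicted = diagnosis$predicted,
         features = as.data.frame(features),
         audit = diagnosis$audit,
         meta = meta),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
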