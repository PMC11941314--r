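# Seeded synthetic recordings whose repetition profiles match configurable
# targets, including the four reference prototypes (normal, chronic, acute,
# pacemaker).  A spec lists target (heart rate, count) pairs intended to fall
# inside the analysis repetition ranges plus background pairs whose counts
# fall outside them (< 1000 or > 3000 by default); the generator realizes
# exactly `count` beats per value, shuffled by a seeded RNG, with timestamps
# accumulating RR = 60000 / hr milliseconds per beat.
#
# When a 5-bpm label recurs in a target profile, distinct heart-rate values
# mapping to that label are assigned deterministically at half-bpm steps
# around the label center (90, 90.5, 89.5, 91, ...).  Half-bpm offsets rather
# than whole-bpm ones: a 5-bpm group contains only five integers, while a
# reference profile can hold six distinct repetition counts in one group.

# printed prototype rows, in published order: repetition count and 5-bpm label
prototype_printed_pairs <- function(class_name) {
  tabs <- list(
    normal = list(
      p1 = cbind(c(1858, 1858, 1814, 1792, 1792, 1780, 1484, 1354, 1331, 1216, 1203),
                 c(90, 85, 65, 90, 85, 70, 70, 60, 55, 70, 60)),
      p2 = cbind(2023, 90)
    ),
    chronic = list(
      p1 = cbind(c(1982, 1938, 1938, 1934, 1659, 1534, 1498, 1484, 1473, 1472,
                   1449, 1419, 1174, 1171, 1162, 1161, 1140, 1122, 1101, 1086,
                   1080, 1065, 1029),
                 c(85, 70, 75, 80, 90, 90, 85, 90, 70, 85, 95, 95, 80, 95, 100,
                   90, 95, 100, 85, 100, 75, 90, 90)),
      p2 = cbind(c(2524, 2496, 2427, 2426, 2184, 2161, 2124, 2094, 2084, 2073),
                 c(80, 75, 75, 80, 75, 70, 70, 85, 80, 85))
    ),
    acute = list(
      p1 = cbind(c(1993, 1921, 1407, 1392, 1316, 1288, 1215, 1202, 1160, 1119, 1087),
                 c(95, 85, 80, 75, 75, 85, 75, 80, 95, 85, 100)),
      p2 = cbind(c(2999, 2997, 2279, 2219), c(90, 100, 90, 80))
    ),
    pacemaker = list(
      p1 = cbind(c(1539, 1536, 1120, 1115), c(75, 65, 70, 60)),
      p2 = cbind(c(2412, 2397), c(65, 60))
    )
  )
  if (!class_name %in% names(tabs)) {
    abort_domain(sprintf("unknown prototype class: %s", class_name))
  }
  t <- tabs[[class_name]]
  m <- rbind(t$p1, t$p2)
  data.frame(count = as.integer(m[, 1L]), label_bpm = as.integer(m[, 2L]))
}

# deterministic half-bpm offsets around a label center; all stay within
# +/- 2 bpm of the label, so the 5-bpm label is preserved
.label_offsets <- c(0, 0.5, -0.5, 1, -1, 1.5, -1.5, 2, -2)

# assign distinct heart-rate values to a label sequence; `used` carries
# occurrence counts per label across calls so backgrounds never collide
# with targets
assign_distinct_hr <- function(labels, used = NULL) {
  if (is.null(used)) used <- new.env(parent = emptyenv())
  hr <- numeric(length(labels))
  for (i in seq_along(labels)) {
    key <- as.character(labels[i])
    k <- if (is.null(used[[key]])) 0L else used[[key]]
    if (k >= length(.label_offsets)) {
      abort_validation(sprintf(
        "more than %d entries share the 5-bpm label %s",
        length(.label_offsets), key
      ))
    }
    hr[i] <- labels[i] + .label_offsets[k + 1L]
    used[[key]] <- k + 1L
  }
  attr(hr, "used") <- used
  hr
}

#' Printed prototype profile as a frequency-repetition table
#'
#' Reconstructs the published (5-bpm label, repetition count) rows of one
#' prototype as a [frequency_table()], assigning deterministic distinct
#' heart-rate values at half-bpm steps when a label recurs (e.g. the chronic
#' prototype holds six counts in the 90-bpm group, realized as 90, 90.5,
#' 89.5, 91, 89 and 91.5).
#'
#' @param class_name One of `"normal"`, `"chronic"`, `"acute"`,
#'   `"pacemaker"`.
#' @return A [frequency_table()] covering both repetition ranges.
#' @export
prototype_table <- function(class_name) {
  rows <- prototype_printed_pairs(class_name)
  hr <- assign_distinct_hr(rows$label_bpm)
  frequency_table(hr_bpm = as.numeric(hr), count = rows$count)
}

#' Construct a synthetic-recording spec
#'
#' @param class_name Target dynamics class, or `"custom"`.
#' @param target_pairs Data frame `hr_bpm,count`; every count must fall inside
#'   one of the analysis `ranges`.
#' @param background_pairs Data frame `hr_bpm,count`; every count must fall
#'   outside all analysis ranges (below the lowest bound or above the
#'   highest).  Heart-rate values must be disjoint from the targets.
#' @param jitter Non-negative integer bound: each realized count is the
#'   specified count plus a seeded uniform integer in `[-jitter, jitter]`.
#'   Rejected if any count could cross a range boundary, which guarantees the
#'   realized profile keeps the spec's per-range pair counts and label
#'   probabilities.
#' @param seed RNG seed used for jitter and beat shuffling.
#' @param ranges Analysis ranges; defaults to [default_ranges()].
#' @param recording_id Identifier for the generated recording.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_name, target_pairs,
                           background_pairs = NULL, jitter = 0L, seed = 1L,
                           ranges = default_ranges(),
                           recording_id = NULL) {
  if (!is.data.frame(target_pairs) ||
      !all(c("hr_bpm", "count") %in% names(target_pairs)) ||
      nrow(target_pairs) == 0L) {
    abort_validation("target_pairs must be a non-empty data frame hr_bpm,count")
  }
  if (is.null(background_pairs)) {
    background_pairs <- data.frame(hr_bpm = numeric(), count = integer())
  }
  if (!is_wholeish(jitter) || jitter < 0) {
    abort_validation("jitter must be a non-negative integer")
  }
  jitter <- as.integer(jitter)
  all_hr <- c(target_pairs$hr_bpm, background_pairs$hr_bpm)
  if (anyDuplicated(all_hr)) {
    abort_validation("target and background hr_bpm values must be disjoint")
  }
  lo_all <- min(vapply(ranges, function(r) r$lo, 1L))
  hi_all <- max(vapply(ranges, function(r) r$hi, 1L))
  for (i in seq_len(nrow(target_pairs))) {
    ct <- target_pairs$count[i]
    hit <- Filter(function(r) ct >= r$lo && ct <= r$hi, ranges)
    if (length(hit) == 0L) {
      abort_validation(sprintf(
        "target count %d (hr %s) falls outside every analysis range",
        ct, target_pairs$hr_bpm[i]
      ))
    }
    r <- hit[[1L]]
    if (ct - jitter < r$lo || ct + jitter > r$hi) {
      abort_validation(sprintf(
        "jitter %d could push target count %d outside range %s [%d, %d]",
        jitter, ct, r$name, r$lo, r$hi
      ))
    }
  }
  if (nrow(background_pairs) > 0L) {
    for (i in seq_len(nrow(background_pairs))) {
      ct <- background_pairs$count[i]
      below <- ct < lo_all
      above <- ct > hi_all
      if (!below && !above) {
        abort_validation(sprintf(
          "background count %d (hr %s) falls inside the analysis ranges",
          ct, background_pairs$hr_bpm[i]
        ))
      }
      if ((below && (ct + jitter >= lo_all || ct - jitter < 1)) ||
          (above && ct - jitter <= hi_all)) {
        abort_validation(sprintf(
          "jitter %d could move background count %d into the analysis ranges",
          jitter, ct
        ))
      }
    }
  }
  if (is.null(recording_id)) {
    recording_id <- sprintf("%s_s%d", class_name, as.integer(seed))
  }
  structure(
    list(class_name = class_name,
         target_pairs = data.frame(hr_bpm = as.numeric(target_pairs$hr_bpm),
                                   count = as.integer(target_pairs$count)),
         background_pairs = data.frame(
           hr_bpm = as.numeric(background_pairs$hr_bpm),
           count = as.integer(background_pairs$count)),
         jitter = jitter, seed = as.integer(seed), ranges = ranges,
         recording_id = as.character(recording_id)),
    class = "synthetic_spec"
  )
}

# class-plausible background: three bulk values (counts > 3000) sized to
# bring the recording near 21 h, plus two rare values (counts < 1000).
# Background mass is not reported for real recordings; these are plausible
# filler, not published values.
.background_layout <- list(
  normal = list(bulk = c(70, 75, 80), rare = c(60, 85)),
  chronic = list(bulk = c(85, 90, 95), rare = c(70, 100)),
  acute = list(bulk = c(85, 90, 95), rare = c(80, 100)),
  pacemaker = list(bulk = c(70, 65, 60), rare = c(75, 65))
)

default_background <- function(class_name, target_pairs, used,
                               duration_s = 21 * 3600) {
  layout <- .background_layout[[class_name]]
  rare_counts <- c(420L, 730L)
  rare_hr <- assign_distinct_hr(layout$rare, used)
  target_s <- sum(target_pairs$count * 60 / target_pairs$hr_bpm)
  rare_s <- sum(rare_counts * 60 / rare_hr)
  remaining_s <- duration_s - target_s - rare_s
  bulk <- NULL
  if (remaining_s > 0) {
    shares <- c(0.5, 0.3, 0.2)
    bulk_hr <- assign_distinct_hr(layout$bulk, used)
    bulk_counts <- pmax(3001L,
                        as.integer(round(shares * remaining_s * bulk_hr / 60)))
    bulk <- data.frame(hr_bpm = bulk_hr, count = bulk_counts)
  }
  rbind(bulk, data.frame(hr_bpm = as.numeric(rare_hr), count = rare_counts))
}

#' Spec reproducing one printed prototype
#'
#' Target pairs realize the printed (label, count) multiset of the prototype
#' via [prototype_table()]; background pairs add class-plausible bulk (counts
#' above 3000 -- for the pacemaker a dominant paced rate -- plus small
#' sub-1000 stragglers) sized so the recording spans roughly 21 hours.
#'
#' @inheritParams prototype_table
#' @param jitter,seed Passed to [synthetic_spec()].
#' @param recording_id Optional identifier.
#' @return A `synthetic_spec`.
#' @export
prototype_spec <- function(class_name, jitter = 0L, seed = 1L,
                           recording_id = NULL) {
  rows <- prototype_printed_pairs(class_name)
  used <- new.env(parent = emptyenv())
  hr <- assign_distinct_hr(rows$label_bpm, used)
  targets <- data.frame(hr_bpm = as.numeric(hr), count = rows$count)
  bg <- default_background(class_name, targets, used)
  synthetic_spec(class_name, targets, bg, jitter = jitter, seed = seed,
                 recording_id = recording_id)
}

#' Generate a synthetic recording from a spec
#'
#' Emits exactly `count` beats per (heart rate, count) pair after seeded
#' jitter, shuffles the beat order with the seeded RNG, and accumulates
#' timestamps at RR = 60000 / hr ms per beat (first beat at time 0).  The
#' returned truth profile equals the realized pair multiset exactly, and
#' identical seeds give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_recording`: list with `series`
#'   (a [beat_series()]), `truth` (a `repetition_profile`) and `spec`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pairs <- rbind(spec$target_pairs, spec$background_pairs)
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(spec$seed)
  counts <- pairs$count
  if (spec$jitter > 0L) {
    counts <- counts + sample(seq(-spec$jitter, spec$jitter),
                              nrow(pairs), replace = TRUE)
  }
  hr_rep <- rep(pairs$hr_bpm, counts)
  hr_seq <- hr_rep[sample.int(length(hr_rep))]
  rr_s <- 60 / hr_seq
  time_s <- c(0, cumsum(rr_s[-length(rr_s)]))
  series <- beat_series(spec$recording_id, time_s, hr_seq)
  truth <- new_repetition_profile(spec$recording_id, pairs$hr_bpm, counts)
  structure(list(series = series, truth = truth, spec = spec),
            class = "synthetic_recording")
}

# save/restore global RNG state so generation is a pure function of the spec
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s (%s): %d beats, %.2f h\n",
              x$spec$recording_id, x$spec$class_name,
              nrow(x$series$beats), x$series$duration_h))
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' `n_per_class` prototype-derived recordings per dynamics class, each with a
#' distinct sub-seed derived deterministically from the master seed, plus a
#' manifest of gold labels.
#'
#' @param n_per_class Recordings per class, at least 1.
#' @param jitter Per-count jitter bound; must keep every count inside its
#'   repetition range (validated per spec), which guarantees in-band features.
#' @param seed Master seed.
#' @param classes Dynamics classes to include.
#' @return List with `recordings` (list of `synthetic_recording`) and
#'   `manifest` (data frame `recording_id,gold`).
#' @export
generate_cohort <- function(n_per_class, jitter = 0L, seed = 1L,
                            classes = DYNAMICS_CLASSES) {
  if (!is_wholeish(n_per_class) || n_per_class < 1) {
    abort_empty("n_per_class must be a positive integer")
  }
  n_per_class <- as.integer(n_per_class)
  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2^30, n_per_class * length(classes))
  recordings <- vector("list", n_per_class * length(classes))
  ids <- character(length(recordings))
  golds <- character(length(recordings))
  k <- 0L
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      rid <- sprintf("%s_%02d", cls, j)
      spec <- prototype_spec(cls, jitter = jitter, seed = sub_seeds[k],
                             recording_id = rid)
      recordings[[k]] <- generate_recording(spec)
      ids[k] <- rid
      golds[k] <- cls
    }
  }
  list(recordings = recordings,
       manifest = data.frame(recording_id = ids, gold = golds))
}

#' Write a synthetic recording to a directory
#'
#' Emits `<id>_beats.csv` (beat dialect of [read_beat_csv()]) and
#' `<id>_truth.csv` (profile dialect `hr_bpm,label_bpm,count`).
#'
#' @param recording A `synthetic_recording`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "synthetic_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- recording$spec$recording_id
  beats <- file.path(dir, paste0(id, "_beats.csv"))
  truth <- file.path(dir, paste0(id, "_truth.csv"))
  write_beat_csv(recording$series, beats)
  write_profile(recording$truth, truth)
  invisible(c(beats = beats, truth = truth))
}
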