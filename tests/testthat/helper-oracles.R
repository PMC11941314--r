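# Independent oracles and frozen expected values shared across tests.

# brute-force "sum of the two largest probabilities": maximum over all
# unordered label pairs (the single probability when only one label exists)
brute_top2 <- function(probs) {
  probs <- unname(probs)
  if (length(probs) == 0L) return(0)
  if (length(probs) == 1L) return(probs)
  cmb <- utils::combn(length(probs), 2L)
  max(probs[cmb[1L, ]] + probs[cmb[2L, ]])
}

# longhand Cohen's kappa on a 2x2 table, written out term by term
kappa_longhand <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) / n) * ((tp + fp) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  if (abs(1 - p_e) < 1e-12) {
    if (abs(1 - p_o) < 1e-12) 1 else NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
}

# brute-force nearest multiple of 5
nearest_label_brute <- function(hr) {
  cand <- seq(0, 5 * ceiling(max(hr) / 5) + 5, by = 5)
  vapply(hr, function(h) {
    d <- abs(cand - h)
    # round half-up on exact midpoints
    winners <- cand[d == min(d)]
    as.integer(max(winners))
  }, 1L)
}

# frozen per-range features of the four reference prototypes, as exact
# fractions worked by hand from the printed tables
proto_expected <- function() {
  data.frame(
    class = rep(c("normal", "chronic", "acute", "pacemaker"), each = 2L),
    range = rep(c("P1", "P2"), times = 4L),
    n_pairs = c(11L, 1L, 23L, 10L, 11L, 4L, 4L, 2L),
    top_sum = c(5 / 11, 1, 10 / 23, 6 / 10, 6 / 11, 3 / 4, 2 / 4, 1),
    freq_min = c(55L, 90L, 70L, 70L, 75L, 80L, 60L, 60L),
    freq_max = c(90L, 90L, 100L, 85L, 100L, 100L, 75L, 65L),
    max_prob = c(3 / 11, 1, 6 / 23, 3 / 10, 3 / 11, 2 / 4, 1 / 4, 1 / 2)
  )
}

# published per-label probabilities (two to three printed decimals)
printed_probs <- function() {
  list(
    normal = list(
      P1 = c(`55` = 0.09, `60` = 0.18, `65` = 0.09, `70` = 0.27,
             `85` = 0.18, `90` = 0.18),
      P2 = c(`90` = 1)
    ),
    chronic = list(
      P1 = c(`70` = 0.087, `75` = 0.087, `80` = 0.087, `85` = 0.17,
             `90` = 0.26, `95` = 0.17, `100` = 0.13),
      P2 = c(`70` = 0.2, `75` = 0.3, `80` = 0.3, `85` = 0.2)
    ),
    acute = list(
      P1 = c(`75` = 0.27, `80` = 0.18, `85` = 0.27, `95` = 0.18, `100` = 0.09),
      P2 = c(`80` = 0.25, `90` = 0.5, `100` = 0.25)
    ),
    pacemaker = list(
      P1 = c(`60` = 0.25, `65` = 0.25, `70` = 0.25, `75` = 0.25),
      P2 = c(`60` = 0.5, `65` = 0.5)
    )
  )
}

prototype_features <- function(class_name) {
  extract_features(profile_from_table(prototype_table(class_name), class_name))
}

# expand a profile back into a beat multiset (uniform spacing is irrelevant
# to repetition counting)
profile_to_series <- function(profile) {
  hr <- rep(profile$entries$hr_bpm, profile$entries$count)
  beat_series(profile$recording_id, seq_along(hr) - 1, hr)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small random profile for property tests
random_profile <- function(n_entries, max_count = 50L) {
  hr <- sample(seq(40, 180, by = 0.5), n_entries)
  frequency_table(hr, sample.int(max_count, n_entries, replace = TRUE))
}
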