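test_that("repetition ranges validate their bounds", {
  r <- repetition_range("P1", 1000, 2000)
  expect_equal(r$lo, 1000L)
  expect_error(repetition_range("bad", 1, 0),
               class = "cardiorep_validation_error")
  expect_error(repetition_range("bad", 0, 10),
               class = "cardiorep_validation_error")
  rngs <- default_ranges()
  expect_equal(vapply(rngs, function(r) c(r$lo, r$hi), c(1, 1)),
               matrix(c(1000, 2000, 2001, 3000), 2,
                      dimnames = list(NULL, c("P1", "P2"))))
})

test_that("filter_range selects exactly the in-range entries", {
  chronic <- profile_from_table(prototype_table("chronic"), "c")
  q1 <- filter_range(chronic, default_ranges()$P1)
  q2 <- filter_range(chronic, default_ranges()$P2)
  expect_equal(nrow(q1), 23L)
  expect_equal(nrow(q2), 10L)
  expect_true(all(q1$count >= 1000 & q1$count <= 2000))
  expect_true(all(q2$count >= 2001 & q2$count <= 3000))
  # nothing lost, nothing doubled: ranges partition 1000-3000
  expect_equal(nrow(q1) + nrow(q2), nrow(chronic$entries[
    chronic$entries$count >= 1000 & chronic$entries$count <= 3000, ]))
})

test_that("range_distribution reproduces the worked per-label fractions", {
  normal <- profile_from_table(prototype_table("normal"), "n")
  d <- range_distribution(filter_range(normal, default_ranges()$P1),
                          default_ranges()$P1)
  expect_equal(d$n_pairs, 11L)
  expect_equal(d$label_probs,
               c(`55` = 1 / 11, `60` = 2 / 11, `65` = 1 / 11, `70` = 3 / 11,
                 `85` = 2 / 11, `90` = 2 / 11))
  expect_equal(d$peak_labels, 70L)
  expect_equal(d$freq_min, 55L)
  expect_equal(d$freq_max, 90L)

  chronic <- profile_from_table(prototype_table("chronic"), "c")
  dc <- range_distribution(filter_range(chronic, default_ranges()$P1),
                           default_ranges()$P1)
  expect_equal(unname(dc$label_probs["90"]), 6 / 23)
  expect_equal(unname(dc$label_probs["70"]), 2 / 23)
  expect_equal(sum(dc$label_probs), 1, tolerance = 1e-12)

  empty <- range_distribution(
    data.frame(label_bpm = integer(), hr_bpm = numeric(), count = integer()),
    default_ranges()$P2)
  expect_equal(empty$n_pairs, 0L)
  expect_equal(empty$top_sum, 0)
  expect_true(is.na(empty$freq_min) && is.na(empty$freq_max))
  expect_length(empty$label_probs, 0L)

  # out-of-range pairs are rejected
  expect_error(
    range_distribution(data.frame(label_bpm = 60L, hr_bpm = 60, count = 10L),
                       default_ranges()$P1),
    class = "cardiorep_validation_error")
})

test_that("top_sum matches its worked examples", {
  rngs <- default_ranges()
  normal <- profile_from_table(prototype_table("normal"), "n")
  expect_equal(top_sum(range_distribution(filter_range(normal, rngs$P1), rngs$P1)),
               5 / 11)
  # single qualifying pair: the statistic is that pair's probability, 1
  expect_equal(top_sum(range_distribution(filter_range(normal, rngs$P2), rngs$P2)),
               1)
  acute <- profile_from_table(prototype_table("acute"), "a")
  expect_equal(top_sum(range_distribution(filter_range(acute, rngs$P2), rngs$P2)),
               0.75)
})

test_that("probabilities normalize and top_sum matches the brute-force oracle", {
  set.seed(19)
  rng <- repetition_range("R", 5, 40)
  for (i in 1:200) {
    tab <- random_profile(sample(2:15, 1), max_count = 45L)
    prof <- profile_from_table(tab, "r")
    d <- range_distribution(filter_range(prof, rng), rng)
    if (d$n_pairs > 0L) {
      expect_equal(sum(d$label_probs), 1, tolerance = 1e-12)
    }
    expect_equal(d$top_sum, brute_top2(d$label_probs), tolerance = 1e-12)
    # monotone bound: top_sum >= max single probability, equality iff <= 1 label
    if (d$n_pairs > 0L) {
      expect_gte(d$top_sum + 1e-12, max(d$label_probs))
      if (length(d$label_probs) > 1L) {
        expect_gt(d$top_sum, max(d$label_probs) - 1e-12)
      }
    }
  }
})

test_that("extract_features assembles per-range records", {
  f <- prototype_features("pacemaker")
  expect_equal(f$n_pairs, c(4L, 2L))
  expect_equal(f$top_sum, c(0.5, 1))
  expect_equal(f$freq_min, c(60L, 60L))
  expect_equal(f$freq_max, c(75L, 65L))

  fa <- prototype_features("acute")
  expect_equal(fa$n_pairs, c(11L, 4L))
  expect_equal(fa$top_sum, c(6 / 11, 0.75))

  fe <- extract_features(profile_from_table(frequency_table(), "e"))
  expect_equal(fe$n_pairs, c(0L, 0L))
  expect_equal(fe$top_sum, c(0, 0))
  expect_true(all(is.na(fe$freq_min)))

  expect_error(
    extract_features(profile_from_table(frequency_table(), "e"),
                     list(A = repetition_range("A", 10, 30),
                          B = repetition_range("B", 25, 50))),
    class = "cardiorep_config_error")
})

test_that("range reports serialize the distributions", {
  f <- prototype_features("chronic")
  js <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  write_range_report(f, js, csv)
  rep <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rep$ranges$P1$n_pairs, 23L)
  expect_equal(rep$ranges$P2$top_sum, 0.6)
  flat <- read.csv(csv)
  expect_equal(sum(flat$range == "P1"), 7L)
  expect_equal(sum(flat$prob[flat$range == "P2"]), 1)
})
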