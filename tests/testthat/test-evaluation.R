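test_that("one-vs-rest confusion counts follow the stated conventions", {
  co <- labeled_cohort(c("a", "b", "c"), rep("acute", 3), rep("acute", 3))
  expect_equal(confusion(co, "acute"), list(tp = 3L, fp = 0L, tn = 0L, fn = 0L))

  co2 <- labeled_cohort(c("a", "b"), c("acute", "normal"), c("acute", "acute"))
  expect_equal(confusion(co2, "acute"), list(tp = 1L, fp = 1L, tn = 0L, fn = 0L))

  # unclassified predictions score against the gold class
  co3 <- labeled_cohort("a", "acute", "unclassified")
  expect_equal(confusion(co3, "acute")$fn, 1L)
  expect_equal(confusion(co3, "normal")$tn, 1L)

  expect_error(confusion(data.frame(), "acute"), class = "cardiorep_empty_error")
})

test_that("sensitivity and specificity handle degenerate denominators", {
  expect_equal(sens_spec(list(tp = 10L, fn = 0L, tn = 15L, fp = 0L)),
               list(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(list(tp = 3L, fn = 1L, tn = 4L, fp = 0L)),
               list(sensitivity = 0.75, specificity = 1))
  ss <- sens_spec(list(tp = 0L, fn = 0L, tn = 4L, fp = 1L))
  expect_true(is.na(ss$sensitivity))
  expect_equal(ss$specificity, 0.8)
})

test_that("cohen_kappa agrees with the longhand formula", {
  # perfect agreement with mixed marginals
  co <- labeled_cohort(letters[1:10],
                       rep(c("acute", "normal"), each = 5),
                       rep(c("acute", "normal"), each = 5))
  expect_equal(cohen_kappa(co, "acute"), 1)

  # worked 2x2 example: TP 4, FN 1, FP 1, TN 4 -> p_o 0.8, p_e 0.5, kappa 0.6
  co2 <- labeled_cohort(
    letters[1:10],
    c(rep("acute", 5), rep("normal", 5)),
    c(rep("acute", 4), "normal", "acute", rep("normal", 4))
  )
  expect_equal(cohen_kappa(co2, "acute"), 0.6)
  expect_equal(kappa_longhand(4, 1, 4, 1), 0.6)

  # random tables: implementation path (cohort) vs longhand formula
  set.seed(23)
  for (i in 1:300) {
    cts <- sample.int(12L, 4L, replace = TRUE)
    gold <- c(rep("pos", cts[1] + cts[4]), rep("neg", cts[2] + cts[3]))
    pred <- c(rep("pos", cts[1]), rep("neg", cts[4]),
              rep("pos", cts[2]), rep("neg", cts[3]))
    co <- labeled_cohort(seq_along(gold), gold, pred)
    expect_equal(cohen_kappa(co, "pos"),
                 kappa_longhand(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-12)
  }
})

test_that("kappa is ~0 when predictions are independent of gold", {
  set.seed(31)
  n <- 4000
  gold <- sample(c("acute", "normal"), n, replace = TRUE)
  pred <- sample(c("acute", "normal"), n, replace = TRUE)
  k <- cohen_kappa(labeled_cohort(seq_len(n), gold, pred), "acute")
  # binomial error on agreement at n = 4000 keeps |kappa| well under 0.06
  expect_lt(abs(k), 0.06)
})

kappa_2x2_via_cohort <- function(tp, fp, tn, fn) {
  gold <- c(rep("pos", tp + fn), rep("neg", fp + tn))
  pred <- c(rep("pos", tp), rep("neg", fn), rep("pos", fp), rep("neg", tn))
  cohen_kappa(labeled_cohort(seq_along(gold), gold, pred), "pos")
}

test_that("kappa is 1 iff the one-vs-rest table has no off-diagonal mass", {
  set.seed(37)
  for (i in 1:50) {
    tp <- sample.int(10L, 1L); tn <- sample.int(10L, 1L)
    fp <- sample(0:3, 1L); fn <- sample(0:3, 1L)
    k <- kappa_2x2_via_cohort(tp, fp, tn, fn)
    if (fp + fn == 0L) expect_equal(k, 1) else expect_lt(k, 1)
  }
})

test_that("evaluation is invariant to cohort order and sums its counts", {
  set.seed(41)
  gold <- sample(c("normal", "chronic", "acute", "pacemaker"), 40, replace = TRUE)
  pred <- gold
  pred[sample.int(40, 6)] <- "unclassified"
  co <- labeled_cohort(seq_len(40), gold, pred)
  ev1 <- evaluate_cohort(co)
  perm <- sample.int(40)
  ev2 <- evaluate_cohort(labeled_cohort(co$recording_id[perm],
                                        co$gold[perm], co$predicted[perm]))
  expect_equal(ev1$per_class, ev2$per_class)
  expect_equal(ev1$pooled_kappa, ev2$pooled_kappa)
  # per-class counts partition the cohort
  expect_true(all(rowSums(ev1$per_class[, c("tp", "fp", "tn", "fn")]) == 40L))
})

test_that("manifests read in both dialects and reject malformed input", {
  p <- write_lines_tmp(c("recording_id,gold,predicted", "a,acute,acute"))
  m <- read_manifest(p)
  expect_false(attr(m, "with_paths"))

  p2 <- write_lines_tmp(c("recording_id,path,gold", "a,/tmp/x.csv,acute"))
  expect_true(attr(read_manifest(p2), "with_paths"))

  empty <- write_lines_tmp("recording_id,gold,predicted")
  expect_error(read_manifest(empty), class = "cardiorep_empty_error")
  bad <- write_lines_tmp(c("id,truth", "a,b"))
  expect_error(read_manifest(bad), class = "cardiorep_format_error")
  dup <- write_lines_tmp(c("recording_id,gold,predicted",
                           "a,acute,acute", "a,normal,normal"))
  expect_error(read_manifest(dup), class = "cardiorep_validation_error")
})
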