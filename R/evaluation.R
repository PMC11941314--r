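# Diagnostic-accuracy evaluation against a gold standard: per-class
# one-vs-rest sensitivity, specificity and Cohen's kappa, plus an overall
# confusion matrix and a pooled multi-class kappa for convenience.
#
# Unclassified predictions are scored as negative for every class: they count
# as false negatives for the gold class and as true negatives elsewhere.
# This is conservative -- an indeterminate call can only hurt agreement.

#' Assemble a labeled cohort
#'
#' @param recording_id Unique identifiers.
#' @param gold Gold-standard class labels.
#' @param predicted Predicted class labels (may include `"unclassified"`).
#' @return A data frame of class `labeled_cohort`.
#' @export
labeled_cohort <- function(recording_id, gold, predicted) {
  if (length(recording_id) == 0L) abort_empty("cohort must be non-empty")
  if (anyDuplicated(recording_id)) {
    abort_validation("recording_id values must be unique")
  }
  if (length(gold) != length(recording_id) ||
      length(predicted) != length(recording_id)) {
    abort_validation("recording_id, gold and predicted must have equal length")
  }
  structure(
    data.frame(recording_id = as.character(recording_id),
               gold = as.character(gold),
               predicted = as.character(predicted)),
    class = c("labeled_cohort", "data.frame")
  )
}

#' One-vs-rest confusion counts for one class
#'
#' Dichotomizes the cohort against `positive_class`: gold and prediction each
#' become positive/negative, and the standard 2x2 counts are returned.
#'
#' @param cohort A [labeled_cohort()] (or plain data frame with `gold` and
#'   `predicted` columns).
#' @param positive_class The class treated as positive.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(cohort, positive_class) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort_empty("cohort must be a non-empty data frame")
  }
  gp <- cohort$gold == positive_class
  pp <- cohort$predicted == positive_class
  list(tp = sum(gp & pp), fp = sum(!gp & pp),
       tn = sum(!gp & !pp), fn = sum(gp & !pp))
}

#' Sensitivity and specificity from one-vs-rest counts
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP).  A zero
#' denominator yields `NA` (absent), never 0.
#'
#' @param counts Counts as returned by [confusion()].
#' @return Named list with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(counts) {
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
          else NA_real_
  spec <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp)
          else NA_real_
  list(sensitivity = sens, specificity = spec)
}

kappa_2x2 <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (n == 0) abort_empty("empty table")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    # degenerate marginals: all mass in one cell
    if (abs(1 - p_o) < 1e-12) 1 else NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
}

#' Cohen's kappa for one class (one-vs-rest)
#'
#' Computes `kappa = (p_o - p_e) / (1 - p_e)` on the dichotomized 2x2 table,
#' where `p_o` is observed agreement and `p_e` the chance agreement implied by
#' the marginals.  When `p_e = 1` (all mass in one cell), kappa is defined as
#' 1 if agreement is perfect and absent (`NA`) otherwise.
#'
#' @inheritParams confusion
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(cohort, positive_class) {
  cts <- confusion(cohort, positive_class)
  kappa_2x2(cts$tp, cts$fp, cts$tn, cts$fn)
}

#' Evaluate a labeled cohort against its gold standard
#'
#' Per class: one-vs-rest counts, sensitivity, specificity and Cohen's kappa.
#' Also reports the full confusion matrix (gold x predicted) and a pooled
#' multi-class kappa.
#'
#' @param cohort A [labeled_cohort()].
#' @param classes Class labels to evaluate; defaults to the gold labels seen.
#' @return An object of class `evaluation_result`: list with `per_class`
#'   (data frame), `confusion_matrix` (table) and `pooled_kappa`.
#' @export
evaluate_cohort <- function(cohort, classes = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort_empty("cohort must be a non-empty data frame")
  }
  if (is.null(classes)) classes <- sort(unique(cohort$gold))
  per <- do.call(rbind, lapply(classes, function(cls) {
    cts <- confusion(cohort, cls)
    ss <- sens_spec(cts)
    data.frame(class = cls, tp = cts$tp, fp = cts$fp, tn = cts$tn,
               fn = cts$fn, sensitivity = ss$sensitivity,
               specificity = ss$specificity,
               kappa = kappa_2x2(cts$tp, cts$fp, cts$tn, cts$fn))
  }))
  lev <- union(classes, unique(c(cohort$gold, cohort$predicted)))
  cm <- table(gold = factor(cohort$gold, levels = lev),
              predicted = factor(cohort$predicted, levels = lev))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  pooled <- if (abs(1 - p_e) < 1e-12) {
    if (abs(1 - p_o) < 1e-12) 1 else NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(
    list(per_class = per, confusion_matrix = cm, pooled_kappa = pooled,
         n = nrow(cohort)),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> n = %d\n", x$n))
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("pooled multi-class kappa: %.4g\n", x$pooled_kappa))
  invisible(x)
}

#' Read a cohort manifest CSV
#'
#' Accepts either `recording_id,gold,predicted` (precomputed predictions) or
#' `recording_id,path,gold` (beat CSVs to be diagnosed in-flow by the caller).
#'
#' @param path Manifest CSV path.
#' @return Data frame with the manifest columns; attribute `"with_paths"`
#'   says which dialect was read.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) abort_empty(sprintf("empty manifest: %s", path))
  if (all(c("recording_id", "gold", "predicted") %in% names(raw))) {
    attr(raw, "with_paths") <- FALSE
  } else if (all(c("recording_id", "path", "gold") %in% names(raw))) {
    attr(raw, "with_paths") <- TRUE
  } else {
    abort_format(
      "manifest needs columns recording_id,gold,predicted or recording_id,path,gold"
    )
  }
  if (anyDuplicated(raw$recording_id)) {
    abort_validation("manifest recording_id values must be unique")
  }
  raw
}

#' Write an evaluation report
#'
#' JSON with the per-class statistics and pooled kappa; optionally the
#' confusion matrix as CSV.
#'
#' @param result An [evaluate_cohort()] result.
#' @param json_path Output JSON path.
#' @param csv_path Optional confusion-matrix CSV path.
#' @param meta Optional named list embedded under `"meta"`.
#' @return `json_path`, invisibly.
#' @export
write_evaluation <- function(result, json_path, csv_path = NULL, meta = NULL) {
  stopifnot(inherits(result, "evaluation_result"))
  cm <- as.data.frame.matrix(result$confusion_matrix)
  jsonlite::write_json(
    list(n = result$n, per_class = result$per_class,
         pooled_kappa = result$pooled_kappa,
         confusion_matrix = cm, meta = meta),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(csv_path)) {
    out <- cbind(gold = rownames(cm), cm)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
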