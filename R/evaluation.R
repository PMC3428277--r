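# Cross-validation, confusion metrics, classifier comparison and
# score-vs-age profiling. Positive class throughout: autism (-1).

as_label_vec <- function(x) {
  if (is.character(x) || is.factor(x)) {
    out <- diagnosis_to_label(as.character(x))
  } else {
    out <- as.integer(x)
  }
  if (any(is.na(out)) || !all(out %in% c(-1L, 1L))) {
    abort("Labels must be -1/+1 or 'autism'/'non_spectrum'.",
          class = "adirshort_validation_error")
  }
  out
}

#' Cross-tabulate truth against predictions
#'
#' @param truth,predicted Equal-length label vectors (-1/+1 integers or
#'   `"autism"`/`"non_spectrum"` strings); autism is the positive class.
#' @return One-row tibble with counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_table(c(-1, -1, 1, 1), c(-1, 1, 1, -1))
#' @export
confusion_table <- function(truth, predicted) {
  if (length(truth) == 0) {
    abort("Cannot build a confusion table from empty input.",
          class = "adirshort_validation_error")
  }
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length.",
          class = "adirshort_validation_error")
  }
  tr <- as_label_vec(truth)
  pr <- as_label_vec(predicted)
  tibble(
    tp = sum(tr == LABEL_AUTISM & pr == LABEL_AUTISM),
    fp = sum(tr == LABEL_NON_SPECTRUM & pr == LABEL_AUTISM),
    tn = sum(tr == LABEL_NON_SPECTRUM & pr == LABEL_NON_SPECTRUM),
    fn = sum(tr == LABEL_AUTISM & pr == LABEL_NON_SPECTRUM)
  )
}

safe_ratio <- function(num, den) {
  ifelse(den > 0, num / den, NA_real_)
}

#' Derived classification metrics
#'
#' Computes FPR = FP/(FP+TN), TPR (sensitivity) = TP/(TP+FN), specificity
#' = 1 - FPR and accuracy = (TP+TN)/total from a confusion table. A metric
#' with a zero denominator is reported as `NA`, never coerced to 0 or 1.
#' Values are unrounded; see [format_metrics()] for presentation rounding.
#'
#' @param ct Confusion-table tibble from [confusion_table()].
#' @return One-row tibble with the counts and `fpr`, `tpr`, `sensitivity`,
#'   `specificity`, `accuracy`, `n`.
#' @examples
#' metrics(tibble::tibble(tp = 891, fn = 0, fp = 1, tn = 74))
#' @export
metrics <- function(ct) {
  total <- ct$tp + ct$fp + ct$tn + ct$fn
  fpr <- safe_ratio(ct$fp, ct$fp + ct$tn)
  tpr <- safe_ratio(ct$tp, ct$tp + ct$fn)
  tibble(
    tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn, n = total,
    fpr = fpr, tpr = tpr, sensitivity = tpr,
    specificity = 1 - fpr,
    accuracy = safe_ratio(ct$tp + ct$tn, total)
  )
}

#' Presentation rounding for metrics
#'
#' Rates to three decimals and accuracy as a percentage with two decimals,
#' mirroring the field's reporting conventions; `NA` stays `"NA"`.
#'
#' @param m Metrics tibble from [metrics()].
#' @return One-row tibble of formatted strings.
#' @export
format_metrics <- function(m) {
  f3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  fpct <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f%%", 100 * x))
  tibble(
    fpr = f3(m$fpr), tpr = f3(m$tpr),
    sensitivity = f3(m$sensitivity), specificity = f3(m$specificity),
    accuracy = fpct(m$accuracy)
  )
}

make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2) abort("k must be >= 2.", class = "adirshort_config_error")
  fold <- integer(n)
  class_sizes <- table(labels)
  withr::with_seed(seed, {
    if (any(class_sizes < k)) {
      warn(sprintf(
        "Smallest class has %d record(s) < k = %d; using unstratified folds.",
        min(class_sizes), k))
      fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    } else {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx[sample.int(length(idx))]] <- rep(seq_len(k), length.out = length(idx))
      }
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the cohort into k folds stratified by class (per-class fold
#' sizes differ by at most one), trains the learner on each k-1-fold
#' training set and scores the held-out fold, so every record is predicted
#' exactly once by a model not trained on it. Falls back to unstratified
#' folds with a warning when a class has fewer than k members.
#'
#' @param recoded Recoded tibble with `label` and item columns.
#' @param learner An `adir_learner` (see [adtree_learner()]).
#' @param k Number of folds (default 10: 90% train / 10% test).
#' @param seed Integer seed for the fold shuffle.
#' @return An object of class `adir_cv`: pooled out-of-fold `predictions`
#'   (subject, fold, truth, score, predicted), the per-fold `models`, and
#'   pooled `metrics`.
#' @export
kfold_cv <- function(recoded, learner, k = 10L, seed = 1L) {
  labels <- as_label_vec(recoded$label)
  fold <- make_folds(labels, k, seed)
  preds <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    train <- recoded[fold != f, , drop = FALSE]
    test <- recoded[fold == f, , drop = FALSE]
    model <- learner$fit(train)
    models[[f]] <- model
    s <- predict_score(model, test)
    preds[[f]] <- tibble(
      subject_id = if ("subject_id" %in% names(test)) test$subject_id else
        as.character(which(fold == f)),
      fold = f,
      truth = as_label_vec(test$label),
      score = s,
      predicted = ifelse(s < 0, LABEL_AUTISM, LABEL_NON_SPECTRUM)
    )
  }
  predictions <- bind_rows(preds)
  structure(
    list(
      predictions = predictions,
      models = models,
      metrics = metrics(confusion_table(predictions$truth, predictions$predicted)),
      k = k, seed = seed, learner_name = learner$name
    ),
    class = "adir_cv"
  )
}

#' @export
print.adir_cv <- function(x, ...) {
  fm <- format_metrics(x$metrics)
  cat(sprintf("%d-fold CV of %s on %d records\n", x$k, x$learner_name,
              nrow(x$predictions)))
  cat(sprintf("  FPR %s  TPR %s  accuracy %s\n", fm$fpr, fm$tpr, fm$accuracy))
  invisible(x)
}

#' @export
tidy.adir_cv <- function(x, ...) {
  x$predictions %>%
    group_by(.data$fold) %>%
    dplyr::group_modify(function(d, g) metrics(confusion_table(d$truth, d$predicted))) %>%
    ungroup()
}

#' @export
glance.adir_cv <- function(x, ...) {
  dplyr::bind_cols(tibble(learner = x$learner_name, k = x$k), x$metrics)
}

#' Compare classifiers by cross-validation
#'
#' Runs the same stratified k-fold cross-validation for each learner and
#' assembles one (FPR, TPR, accuracy) row per classifier — the
#' 1-specificity versus sensitivity comparison. Externally computed rows
#' (e.g. published results for algorithms not implemented here) are
#' appended verbatim.
#'
#' @param recoded Recoded tibble.
#' @param learners List of `adir_learner` objects (may be empty).
#' @param external Optional tibble with columns `classifier`, `fpr`, `tpr`,
#'   `accuracy`, appended unchanged.
#' @param k,seed Cross-validation parameters.
#' @return Tibble of class `adir_comparison` with one row per classifier
#'   and a `source` column (`"cv"` or `"external"`).
#' @export
compare_classifiers <- function(recoded, learners, external = NULL,
                                k = 10L, seed = 1L) {
  rows <- purrr::map_dfr(learners, function(ln) {
    cv <- kfold_cv(recoded, ln, k = k, seed = seed)
    tibble(classifier = ln$name, fpr = cv$metrics$fpr, tpr = cv$metrics$tpr,
           accuracy = cv$metrics$accuracy, source = "cv")
  })
  if (!is.null(external) && nrow(external) > 0) {
    ext <- as_tibble(external)[, c("classifier", "fpr", "tpr", "accuracy")]
    ext$source <- "external"
    rows <- bind_rows(rows, ext)
  }
  if (nrow(rows) == 0) {
    abort("Nothing to compare: no learners and no external rows.",
          class = "adirshort_config_error")
  }
  class(rows) <- c("adir_comparison", class(rows))
  rows
}

#' Score-versus-age profile of a fitted classifier
#'
#' Scores every subject in a cohort and tabulates the signed score against
#' age in years, with the truth label, predicted label and low-confidence
#' flag — the scatter used to inspect whether classifications hold across
#' ages.
#'
#' @param model A fitted model supporting [predict_score()].
#' @param sheets Answer-sheet tibble with `age_months` and raw item codes.
#' @param band Low-confidence band half-width (see [classify_score()]).
#' @return Tibble of class `adir_score_profile`: `subject_id`, `age_years`,
#'   `score`, `truth`, `predicted`, `confidence`, `low_confidence`.
#' @export
score_profile <- function(model, sheets, band = 0.5) {
  rec <- recode_cohort(sheets)
  s <- predict_score(model, rec)
  cl <- classify_score(s, band = band)
  out <- tibble(
    subject_id = rec$subject_id,
    age_years = rec$age_months / 12,
    score = s,
    truth = label_to_diagnosis(rec$label),
    predicted = cl$diagnosis,
    confidence = cl$confidence,
    low_confidence = cl$low_confidence
  )
  class(out) <- c("adir_score_profile", class(out))
  out
}
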