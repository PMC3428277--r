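# Simple comparison learners sharing the ADTree fit/predict contract:
# a one-split decision stump and a OneR single-attribute rule learner.
# Both emit scores of constant amplitude 1 so evaluation code can treat
# every classifier uniformly (sign = class, |score| = confidence).

majority_label <- function(n_pos, n_neg) {
  # Ties resolve toward autism (-1): in a screening instrument a false
  # negative is costlier than a false positive.
  ifelse(n_pos > n_neg, LABEL_NON_SPECTRUM, LABEL_AUTISM)
}

#' Fit a decision stump
#'
#' A single-level decision tree: one item, one threshold, one label per
#' side. The stump minimising training misclassifications is chosen, each
#' side labelled by its weighted majority class (ties toward autism).
#' Equal-error ties resolve to the lowest item index, then the lowest
#' threshold. When no item has two distinct values the stump degenerates to
#' a constant majority-class predictor.
#'
#' @param recoded Recoded tibble with `label` and item columns.
#' @return An object of class `stump_model` with fields `item`,
#'   `threshold`, `label_lo`, `label_hi` and `train_errors`.
#' @export
fit_stump <- function(recoded) {
  X <- recoded_to_matrix(recoded)
  y <- as.integer(recoded$label)
  if (nrow(X) == 0) abort("Cannot fit on an empty matrix.", class = "adirshort_validation_error")
  items <- colnames(X)
  best <- NULL
  for (j in seq_along(items)) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (thr in (head(v, -1) + tail(v, -1)) / 2) {
      lo <- X[, j] < thr
      lab_lo <- majority_label(sum(y[lo] > 0), sum(y[lo] < 0))
      lab_hi <- majority_label(sum(y[!lo] > 0), sum(y[!lo] < 0))
      pred <- ifelse(lo, lab_lo, lab_hi)
      err <- sum(pred != y)
      if (is.null(best) || err < best$train_errors) {
        best <- list(item = items[j], threshold = thr, label_lo = lab_lo,
                     label_hi = lab_hi, train_errors = err)
      }
    }
  }
  if (is.null(best)) {
    lab <- majority_label(sum(y > 0), sum(y < 0))
    best <- list(item = items[1] %||% NA_character_, threshold = -Inf,
                 label_lo = lab, label_hi = lab,
                 train_errors = sum(y != lab))
  }
  structure(best, class = "stump_model")
}

#' @export
predict_score.stump_model <- function(model, newdata) {
  if (is.finite(model$threshold)) {
    X <- recoded_to_matrix(newdata, items = model$item)
    as.numeric(ifelse(X[, model$item] < model$threshold,
                      model$label_lo, model$label_hi))
  } else {
    n <- nrow(newdata)
    rep(as.numeric(model$label_hi), n)
  }
}

#' @export
predict.stump_model <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  s <- predict_score(object, newdata)
  if (type == "score") s else as.integer(sign(s))
}

#' Fit a OneR rule learner
#'
#' For every item, each observed score value is mapped to its majority
#' label (value-level ties toward autism); the item whose rule makes the
#' fewest training errors is selected (ties to the lowest item index).
#' Values unseen in training fall back to the overall majority label.
#'
#' @param recoded Recoded tibble with `label` and item columns.
#' @return An object of class `oner_model` with fields `item`, `mapping`
#'   (named integer vector, score value as name -> label), `default_label`
#'   and `train_errors`.
#' @export
fit_oner <- function(recoded) {
  X <- recoded_to_matrix(recoded)
  y <- as.integer(recoded$label)
  if (nrow(X) == 0) abort("Cannot fit on an empty matrix.", class = "adirshort_validation_error")
  items <- colnames(X)
  best <- NULL
  for (j in seq_along(items)) {
    vals <- sort(unique(X[, j]))
    mapping <- integer(0)
    err <- 0L
    for (v in vals) {
      sel <- X[, j] == v
      lab <- majority_label(sum(y[sel] > 0), sum(y[sel] < 0))
      mapping[as.character(v)] <- lab
      err <- err + sum(y[sel] != lab)
    }
    if (is.null(best) || err < best$train_errors) {
      best <- list(item = items[j], mapping = mapping, train_errors = err)
    }
  }
  best$default_label <- majority_label(sum(y > 0), sum(y < 0))
  structure(best, class = "oner_model")
}

#' @export
predict_score.oner_model <- function(model, newdata) {
  X <- recoded_to_matrix(newdata, items = model$item)
  lab <- model$mapping[as.character(X[, model$item])]
  lab[is.na(lab)] <- model$default_label
  as.numeric(unname(lab))
}

#' @export
predict.oner_model <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  s <- predict_score(object, newdata)
  if (type == "score") s else as.integer(sign(s))
}

#' Learner specifications for cross-validation
#'
#' Thin wrappers pairing a display name with a fitting function, so
#' [kfold_cv()] and [compare_classifiers()] can treat the ADTree and the
#' baselines uniformly.
#'
#' @param iterations,epsilon ADTree training parameters (see
#'   [fit_adtree()]).
#' @return An object of class `adir_learner`: a list with `name` and
#'   `fit(recoded)`.
#' @export
adtree_learner <- function(iterations = 10L, epsilon = 1) {
  structure(list(
    name = "ADTree",
    fit = function(recoded) fit_adtree(recoded, iterations = iterations,
                                       epsilon = epsilon)
  ), class = "adir_learner")
}

#' @rdname adtree_learner
#' @export
stump_learner <- function() {
  structure(list(name = "DecisionStump", fit = fit_stump), class = "adir_learner")
}

#' @rdname adtree_learner
#' @export
oner_learner <- function() {
  structure(list(name = "OneR", fit = fit_oner), class = "adir_learner")
}
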