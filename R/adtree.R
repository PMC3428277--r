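# Alternating decision tree (ADTree) learner and model.
#
# An ADTree alternates prediction nodes (real-valued additive contributions)
# and splitter nodes (threshold tests on one item). A sheet's score is the
# sum of the values of every prediction node it reaches; the root is always
# reached, and a splitter's child is reached iff its parent prediction node
# is reached and the threshold condition holds. The sign of the score is the
# class (negative = autism), its amplitude a measure of confidence.
#
# Training is boosting over "base rules" (precondition c1 = an existing
# prediction-node path, condition c2 = one threshold test). Each iteration
# adds the splitter minimising
#   Z(c1,c2) = 2*[sqrt(W+(c1&c2) W-(c1&c2)) + sqrt(W+(c1&!c2) W-(c1&!c2))]
#              + W(!c1)
# where W+/W- are the weights of positive/negative records satisfying a
# predicate; child values are 1/2*log((W+ + eps)/(W- + eps)) on their
# partitions and record weights update by exp(-y * contribution).

# Ties in Z within this tolerance are resolved by (item index, threshold,
# path creation order); keeps selection stable under float summation order.
Z_TIE_TOL <- 1e-12

new_adtree <- function(root_value, items, epsilon, metadata = list()) {
  structure(
    list(
      pred_nodes = tibble(
        pred_id = 1L, value = as.numeric(root_value),
        parent_split = NA_integer_, side = NA_character_, created = 1L
      ),
      splits = tibble(
        split_id = integer(), parent_pred = integer(), item = character(),
        threshold = numeric(), lo_pred = integer(), hi_pred = integer()
      ),
      items = items,
      epsilon = epsilon,
      history = tibble(
        iter = integer(), parent_pred = integer(), item = character(),
        threshold = numeric(), z = numeric(), lo_value = numeric(),
        hi_value = numeric(), loss = numeric()
      ),
      metadata = metadata
    ),
    class = "adtree"
  )
}

# Manually graft a splitter under prediction node `pred_id`; used to build
# reference trees in tests and documentation examples.
adtree_add_split <- function(model, pred_id, item, threshold, lo_value, hi_value) {
  sid <- nrow(model$splits) + 1L
  np <- nrow(model$pred_nodes)
  lo_id <- np + 1L
  hi_id <- np + 2L
  model$pred_nodes <- bind_rows(
    model$pred_nodes,
    tibble(pred_id = c(lo_id, hi_id), value = c(lo_value, hi_value),
           parent_split = sid, side = c("lo", "hi"), created = c(lo_id, hi_id))
  )
  model$splits <- bind_rows(
    model$splits,
    tibble(split_id = sid, parent_pred = pred_id, item = item,
           threshold = threshold, lo_pred = lo_id, hi_pred = hi_id)
  )
  if (!item %in% model$items) model$items <- c(model$items, item)
  model
}

half_log_ratio <- function(w_pos, w_neg, eps) {
  0.5 * log((w_pos + eps) / (w_neg + eps))
}

recoded_to_matrix <- function(recoded, items = NULL) {
  if (is.matrix(recoded)) {
    if (!is.null(items)) {
      missing_items <- setdiff(items, colnames(recoded))
      if (length(missing_items) > 0) {
        abort(paste0("Input lacks model item(s): ",
                     paste(missing_items, collapse = ", ")),
              class = "adirshort_validation_error")
      }
      recoded <- recoded[, items, drop = FALSE]
    }
    return(recoded)
  }
  cols <- if (is.null(items)) item_cols(recoded) else items
  missing_items <- setdiff(cols, names(recoded))
  if (length(missing_items) > 0) {
    abort(paste0("Input lacks model item(s): ",
                 paste(missing_items, collapse = ", ")),
          class = "adirshort_validation_error")
  }
  m <- as.matrix(as.data.frame(recoded[, cols, drop = FALSE]))
  storage.mode(m) <- "numeric"
  m
}

#' Fit an alternating decision tree
#'
#' Boosted ADTree training on a recoded matrix with labels in \{-1, +1\}
#' (autism = -1, non-spectrum = +1). Record weights start at 1; the root
#' prediction value is the smoothed half-log-ratio of class weights (rule 0,
#' with the corresponding weight update); each of the `iterations` rounds
#' exhaustively searches all (existing prediction node) x (item, threshold)
#' base rules for the minimiser of the Z-criterion and grafts a splitter
#' whose two child values are smoothed half-log-ratios on their partitions.
#' Candidate thresholds are midpoints between consecutive observed scores of
#' an item among the records reaching the precondition node. Records are
#' canonically re-ordered internally, so the fit is invariant to row
#' permutation.
#'
#' @param recoded Recoded tibble with a `label` column and item score
#'   columns (see [recode_cohort()]), or a numeric matrix plus `labels`.
#' @param iterations Number of boosting rounds (splitter nodes), default 10.
#' @param epsilon Smoothing constant added to both weights in every
#'   half-log-ratio, default 1.
#' @param labels Optional label vector when `recoded` is a bare matrix.
#' @return An object of class `adtree` with prediction-node and splitter
#'   tables, the per-iteration search history (chosen rule, Z, exponential
#'   loss), and the training item order.
#' @examples
#' rec <- tibble::tibble(
#'   label = c(-1L, -1L, 1L, 1L),
#'   a = c(2L, 2L, 0L, 0L), b = c(1L, 0L, 1L, 0L)
#' )
#' fit <- fit_adtree(rec, iterations = 1)
#' tidy(fit)
#' @export
fit_adtree <- function(recoded, iterations = 10L, epsilon = 1,
                       labels = NULL) {
  if (iterations < 0) abort("iterations must be >= 0.", class = "adirshort_config_error")
  if (epsilon <= 0) abort("epsilon must be > 0.", class = "adirshort_config_error")
  if (is.matrix(recoded)) {
    X <- recoded_to_matrix(recoded)
    y <- as.numeric(labels)
  } else {
    X <- recoded_to_matrix(recoded)
    y <- as.numeric(recoded$label)
  }
  if (nrow(X) == 0) abort("Cannot fit on an empty matrix.", class = "adirshort_validation_error")
  if (!all(y %in% c(-1, 1))) {
    abort("Labels must be -1 (autism) or +1 (non-spectrum).",
          class = "adirshort_validation_error")
  }
  items <- colnames(X)
  if (is.null(items)) {
    items <- paste0("x", seq_len(ncol(X)))
    colnames(X) <- items
  }

  # Canonical record order: permutation-invariant fits.
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(X)

  single_class <- length(unique(y)) < 2
  if (single_class && iterations > 0) {
    warn("Training data contain a single class; returning a root-only model.")
    iterations <- 0L
  }

  w <- rep(1, n)
  root_value <- half_log_ratio(sum(w[y > 0]), sum(w[y < 0]), epsilon)
  w <- w * exp(-y * root_value)

  model <- new_adtree(root_value, items, epsilon,
                      metadata = list(n_train = n,
                                      n_autism = sum(y < 0),
                                      n_non_spectrum = sum(y > 0)))
  model$history <- tibble(
    iter = 0L, parent_pred = NA_integer_, item = NA_character_,
    threshold = NA_real_, z = NA_real_, lo_value = root_value,
    hi_value = NA_real_, loss = sum(w)
  )

  # Per-item global value grid and candidate (threshold, flanking values).
  item_values <- lapply(seq_along(items), function(j) sort(unique(X[, j])))
  cand <- purrr::map_dfr(seq_along(items), function(j) {
    v <- item_values[[j]]
    if (length(v) < 2) return(tibble())
    pairs <- utils::combn(seq_along(v), 2)
    tibble(
      item_idx = j,
      lo_val = v[pairs[1, ]], hi_val = v[pairs[2, ]],
      threshold = (v[pairs[1, ]] + v[pairs[2, ]]) / 2
    )
  })
  if (nrow(cand) == 0) iterations <- min(iterations, 0L)

  if (iterations > 0) {
    # n x n_candidates condition indicators: x_item < threshold.
    cond_mat <- matrix(FALSE, n, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      cond_mat[, k] <- X[, cand$item_idx[k]] < cand$threshold[k]
    }
    # n x n_candidates "value observed strictly between flanks" indicator and
    # per-flank membership, to decide per-path candidate validity.
    at_lo <- matrix(FALSE, n, nrow(cand))
    at_hi <- matrix(FALSE, n, nrow(cand))
    between <- matrix(FALSE, n, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      xj <- X[, cand$item_idx[k]]
      at_lo[, k] <- xj == cand$lo_val[k]
      at_hi[, k] <- xj == cand$hi_val[k]
      between[, k] <- xj > cand$lo_val[k] & xj < cand$hi_val[k]
    }
    storage.mode(cond_mat) <- "numeric"
    storage.mode(at_lo) <- "numeric"
    storage.mode(at_hi) <- "numeric"
    storage.mode(between) <- "numeric"

    reach <- matrix(TRUE, n, 1) # columns follow pred_id
    total_iters <- iterations
    t <- 0L
    while (t < total_iters) {
      t <- t + 1L
      wpos <- w * (y > 0)
      wneg <- w * (y < 0)
      total_w <- sum(w)
      best <- NULL
      cand_rows <- list()
      for (p in seq_len(ncol(reach))) {
        mask <- as.numeric(reach[, p])
        if (!any(mask > 0)) next
        n_lo <- as.numeric(crossprod(at_lo, mask))
        n_hi <- as.numeric(crossprod(at_hi, mask))
        n_between <- as.numeric(crossprod(between, mask))
        valid <- n_lo > 0 & n_hi > 0 & n_between == 0
        if (!any(valid)) next
        wp_path <- sum(wpos * mask)
        wn_path <- sum(wneg * mask)
        w_not <- total_w - wp_path - wn_path
        wp_lo <- as.numeric(crossprod(cond_mat, wpos * mask))
        wn_lo <- as.numeric(crossprod(cond_mat, wneg * mask))
        wp_hi <- pmax(wp_path - wp_lo, 0)
        wn_hi <- pmax(wn_path - wn_lo, 0)
        z <- 2 * (sqrt(wp_lo * wn_lo) + sqrt(wp_hi * wn_hi)) + w_not
        idx <- which(valid)
        cand_rows[[length(cand_rows) + 1L]] <- tibble(
          path = p,
          item_idx = cand$item_idx[idx],
          threshold = cand$threshold[idx],
          z = z[idx],
          wp_lo = wp_lo[idx], wn_lo = wn_lo[idx],
          wp_hi = wp_hi[idx], wn_hi = wn_hi[idx]
        )
      }
      if (length(cand_rows) == 0) {
        warn(sprintf("No admissible split at iteration %d; stopping early.", t))
        break
      }
      all_cand <- bind_rows(cand_rows)
      zmin <- min(all_cand$z)
      tied <- all_cand[all_cand$z <= zmin + Z_TIE_TOL, , drop = FALSE]
      tied <- tied[order(tied$item_idx, tied$threshold, tied$path), , drop = FALSE]
      best <- tied[1, ]

      a_lo <- half_log_ratio(best$wp_lo, best$wn_lo, epsilon)
      a_hi <- half_log_ratio(best$wp_hi, best$wn_hi, epsilon)
      item_abbr <- items[best$item_idx]
      model <- adtree_add_split(model, pred_id = best$path, item = item_abbr,
                                threshold = best$threshold,
                                lo_value = a_lo, hi_value = a_hi)
      cond_best <- X[, best$item_idx] < best$threshold
      reach_lo <- reach[, best$path] & cond_best
      reach_hi <- reach[, best$path] & !cond_best
      reach <- cbind(reach, reach_lo, reach_hi)
      w[reach_lo] <- w[reach_lo] * exp(-y[reach_lo] * a_lo)
      w[reach_hi] <- w[reach_hi] * exp(-y[reach_hi] * a_hi)

      model$history <- bind_rows(model$history, tibble(
        iter = t, parent_pred = as.integer(best$path), item = item_abbr,
        threshold = best$threshold, z = best$z,
        lo_value = a_lo, hi_value = a_hi, loss = sum(w)
      ))
    }
  }
  model$iterations_used <- nrow(model$splits)
  model
}

#' Score sheets with a fitted ADTree
#'
#' The score of a sheet is the sum of the values of every prediction node it
#' reaches: the root always contributes, and each splitter routes the sheet
#' to its low child (`score < threshold`) or high child (`score >=
#' threshold`) only when the splitter's parent prediction node was reached.
#' Multiple parallel paths all contribute.
#'
#' @param model A fitted `adtree`.
#' @param newdata Recoded tibble or numeric matrix containing every item the
#'   model references.
#' @return Numeric vector of signed scores (negative = autism).
#' @export
predict_score <- function(model, newdata) {
  UseMethod("predict_score")
}

#' @export
predict_score.adtree <- function(model, newdata) {
  used <- unique(model$splits$item)
  X <- recoded_to_matrix(newdata, items = if (length(used)) used else NULL)
  n <- if (is.matrix(X)) nrow(X) else nrow(newdata)
  if (n == 0) return(numeric(0))
  reach <- matrix(FALSE, n, nrow(model$pred_nodes))
  reach[, 1] <- TRUE
  if (nrow(model$splits) > 0) {
    for (s in seq_len(nrow(model$splits))) {
      sp <- model$splits[s, ]
      cond <- X[, sp$item] < sp$threshold
      reach[, sp$lo_pred] <- reach[, sp$parent_pred] & cond
      reach[, sp$hi_pred] <- reach[, sp$parent_pred] & !cond
    }
  }
  as.numeric(reach %*% model$pred_nodes$value)
}

#' @export
predict.adtree <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  s <- predict_score(object, newdata)
  if (type == "score") s else ifelse(s < 0, LABEL_AUTISM, LABEL_NON_SPECTRUM)
}

#' Classify signed scores with confidence
#'
#' A negative score classifies as autism, a non-negative score as
#' non-spectrum (zero resolves to non-spectrum and is always flagged). The
#' score's amplitude is the confidence; scores inside the low-confidence
#' band are flagged for closer inspection and further behavioural
#' assessment.
#'
#' @param score Numeric vector of classifier scores.
#' @param band Non-negative half-width of the low-confidence band
#'   (default 0.5).
#' @return Tibble with `score`, `diagnosis`, `label` (-1/+1), `confidence`
#'   (= |score|) and `low_confidence`.
#' @examples
#' classify_score(c(-3.2, 0.179, 0))
#' @export
classify_score <- function(score, band = 0.5) {
  if (band < 0) abort("band must be non-negative.", class = "adirshort_config_error")
  if (any(!is.finite(score))) {
    abort("Scores must be finite.", class = "adirshort_validation_error")
  }
  label <- ifelse(score < 0, LABEL_AUTISM, LABEL_NON_SPECTRUM)
  tibble(
    score = as.numeric(score),
    diagnosis = label_to_diagnosis(label),
    label = as.integer(label),
    confidence = abs(score),
    low_confidence = abs(score) < band | score == 0
  )
}

#' Items used by a fitted ADTree
#'
#' @param model A fitted `adtree`.
#' @return Tibble with one row per distinct item appearing in a splitter
#'   node and its `multiplicity` (number of splitters testing it).
#' @export
extract_items <- function(model) {
  if (nrow(model$splits) == 0) {
    return(tibble(item = character(), multiplicity = integer()))
  }
  model$splits %>%
    count(.data$item, name = "multiplicity") %>%
    arrange(.data$item)
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("ADTree model: %d splitter(s), root value %.4f\n",
              nrow(x$splits), x$pred_nodes$value[1]))
  if (nrow(x$splits) > 0) {
    it <- extract_items(x)
    cat(sprintf("Items used (%d distinct): %s\n", nrow(it),
                paste(sprintf("%s x%d", it$item, it$multiplicity), collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ADTree model
#'
#' @param x A fitted `adtree`.
#' @param ... Unused.
#' @return One row per boosting iteration: chosen item, threshold, Z value,
#'   low/high child prediction values, exponential loss after the update.
#'   Iteration 0 is the root rule.
#' @export
tidy.adtree <- function(x, ...) {
  x$history
}

#' @rdname tidy.adtree
#' @return `glance()`: a one-row summary (iterations used, distinct items,
#'   root value, final exponential loss, training composition).
#' @export
glance.adtree <- function(x, ...) {
  tibble(
    iterations = nrow(x$splits),
    n_items = nrow(extract_items(x)),
    root_value = x$pred_nodes$value[1],
    train_loss = tail(x$history$loss, 1),
    n_train = x$metadata$n_train %||% NA_integer_,
    n_autism = x$metadata$n_autism %||% NA_integer_,
    n_non_spectrum = x$metadata$n_non_spectrum %||% NA_integer_
  )
}
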