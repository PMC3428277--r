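# Independent brute-force oracles used to cross-check the learners.
# These deliberately share no code with the package implementations:
# naive loops and direct formula evaluation only.

# Enumerate every (prediction-node path, item, threshold) base rule and run
# the boosting recursion by hand. Returns the root value and a per-iteration
# trace (parent path id in creation order, item name, threshold, Z, child
# values).
oracle_fit_adtree <- function(X, y, iterations, eps = 1) {
  n <- nrow(X)
  w <- rep(1, n)
  root <- 0.5 * log((sum(w[y > 0]) + eps) / (sum(w[y < 0]) + eps))
  w <- w * exp(-y * root)
  paths <- list(rep(TRUE, n)) # index = prediction-node creation id
  hist <- list()
  for (t in seq_len(iterations)) {
    cands <- list()
    for (p in seq_along(paths)) {
      mask <- paths[[p]]
      if (!any(mask)) next
      for (j in seq_len(ncol(X))) {
        vals <- sort(unique(X[mask, j]))
        if (length(vals) < 2) next
        for (i in seq_len(length(vals) - 1)) {
          thr <- (vals[i] + vals[i + 1]) / 2
          lo <- mask & (X[, j] < thr)
          hi <- mask & !(X[, j] < thr)
          Wpl <- sum(w[lo & y > 0]); Wnl <- sum(w[lo & y < 0])
          Wph <- sum(w[hi & y > 0]); Wnh <- sum(w[hi & y < 0])
          z <- 2 * (sqrt(Wpl * Wnl) + sqrt(Wph * Wnh)) + sum(w[!mask])
          cands[[length(cands) + 1]] <- list(
            path = p, item = j, thr = thr, z = z,
            Wpl = Wpl, Wnl = Wnl, Wph = Wph, Wnh = Wnh
          )
        }
      }
    }
    if (length(cands) == 0) break
    zs <- vapply(cands, function(c) c$z, numeric(1))
    tied <- cands[zs <= min(zs) + 1e-12]
    ord <- order(vapply(tied, function(c) c$item, numeric(1)),
                 vapply(tied, function(c) c$thr, numeric(1)),
                 vapply(tied, function(c) c$path, numeric(1)))
    b <- tied[[ord[1]]]
    a_lo <- 0.5 * log((b$Wpl + eps) / (b$Wnl + eps))
    a_hi <- 0.5 * log((b$Wph + eps) / (b$Wnh + eps))
    mask <- paths[[b$path]]
    lo <- mask & (X[, b$item] < b$thr)
    hi <- mask & !(X[, b$item] < b$thr)
    w[lo] <- w[lo] * exp(-y[lo] * a_lo)
    w[hi] <- w[hi] * exp(-y[hi] * a_hi)
    paths <- c(paths, list(lo), list(hi))
    hist[[t]] <- data.frame(
      iter = t, parent = b$path, item = colnames(X)[b$item],
      threshold = b$thr, z = b$z, lo_value = a_lo, hi_value = a_hi,
      loss = sum(w)
    )
  }
  list(root = root, history = do.call(rbind, hist), final_loss = sum(w))
}

# Path-enumeration scoring oracle: recursive descent summing every reached
# prediction node, independent of the package's reach-matrix computation.
oracle_score <- function(model, x) {
  walk <- function(pred_id) {
    total <- model$pred_nodes$value[model$pred_nodes$pred_id == pred_id]
    kids <- model$splits[model$splits$parent_pred == pred_id, , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      sp <- kids[i, ]
      child <- if (x[[sp$item]] < sp$threshold) sp$lo_pred else sp$hi_pred
      total <- total + walk(child)
    }
    total
  }
  walk(1L)
}

# Exhaustive decision-stump search: minimum training misclassifications
# over every (item, threshold, side-label) assignment.
oracle_best_stump_errors <- function(X, y) {
  best <- sum(y != ifelse(sum(y > 0) > sum(y < 0), 1, -1))
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      lo <- X[, j] < thr
      for (ll in c(-1, 1)) for (lh in c(-1, 1)) {
        err <- sum(y != ifelse(lo, ll, lh))
        if (err < best) best <- err
      }
    }
  }
  best
}

# Exhaustive OneR search: per item, majority label per observed value.
oracle_best_oner <- function(X, y) {
  errs <- vapply(seq_len(ncol(X)), function(j) {
    tot <- 0
    for (v in unique(X[, j])) {
      sel <- X[, j] == v
      tot <- tot + min(sum(y[sel] > 0), sum(y[sel] < 0))
    }
    tot
  }, numeric(1))
  list(item = which.min(errs), errors = min(errs))
}

# Random small recoded problems for property-style tests.
random_recoded <- function(n, n_items, seed) {
  withr::with_seed(seed, {
    X <- matrix(sample(0:2, n * n_items, replace = TRUE), n, n_items,
                dimnames = list(NULL, paste0("it", seq_len(n_items))))
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(y)) == 1) y[1] <- -y[1]
  })
  list(X = X, y = y,
       rec = dplyr::bind_cols(tibble::tibble(label = y),
                              tibble::as_tibble(as.data.frame(X))))
}
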