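test_that("a single-class cohort yields a root-only model with the right sign", {
  rec <- tibble::tibble(label = rep(1L, 6), a = c(0L, 1L, 2L, 0L, 1L, 2L))
  m0 <- fit_adtree(rec, iterations = 0)
  expect_equal(nrow(m0$splits), 0)
  expect_gt(m0$pred_nodes$value[1], 0)
  expect_true(all(predict_score(m0, rec) > 0))
  expect_warning(m1 <- fit_adtree(rec, iterations = 3), "single class")
  expect_equal(nrow(m1$splits), 0)
})

test_that("a perfectly separable single item is found with hand-computed values", {
  rec <- tibble::tibble(
    label = c(rep(1L, 4), rep(-1L, 4)),
    a = c(rep(0L, 4), rep(2L, 4)),
    b = rep(1L, 8)
  )
  m <- fit_adtree(rec, iterations = 1)
  expect_equal(nrow(m$splits), 1)
  expect_equal(m$splits$item, "a")
  expect_equal(m$splits$threshold, 1.0)
  # root: balanced classes -> 0; children: 1/2*log((4+1)/(0+1)) on each side
  expect_equal(m$pred_nodes$value[1], 0)
  expect_equal(m$pred_nodes$value[2], 0.5 * log(5))
  expect_equal(m$pred_nodes$value[3], -0.5 * log(5))
  pred <- predict(m, rec, type = "label")
  expect_equal(pred, rec$label)
})

test_that("chosen splits and values match the brute-force Z enumeration oracle", {
  cases <- expand.grid(n = c(6, 9, 12), p = c(2, 3), t_max = c(1, 2),
                       rep = 1:3)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    inst <- random_recoded(cs$n, cs$p, seed = 1000 + i)
    fit <- fit_adtree(inst$rec, iterations = cs$t_max)
    orc <- oracle_fit_adtree(inst$X, as.numeric(inst$y), cs$t_max)
    expect_equal(fit$pred_nodes$value[1], orc$root)
    hist <- fit$history[fit$history$iter > 0, ]
    expect_equal(nrow(hist), NROW(orc$history))
    if (NROW(orc$history) > 0) {
      expect_equal(hist$parent_pred, orc$history$parent)
      expect_equal(hist$item, orc$history$item)
      expect_equal(hist$threshold, orc$history$threshold)
      expect_equal(hist$z, orc$history$z)
      expect_equal(hist$lo_value, orc$history$lo_value)
      expect_equal(hist$hi_value, orc$history$hi_value)
      expect_equal(hist$loss, orc$history$loss)
    }
  }
})

test_that("exponential loss is non-increasing and strictly decreases on planted signal", {
  rec <- recode_cohort(small_cohort(seed = 21))
  m <- fit_adtree(rec, iterations = 10)
  expect_true(all(diff(m$history$loss) < 0))
  # loss recomputed independently from scores must match the internal log
  s <- predict_score(m, rec)
  expect_equal(sum(exp(-rec$label * s)), tail(m$history$loss, 1))
  # random labels: still never increasing
  inst <- random_recoded(30, 4, seed = 77)
  m2 <- fit_adtree(inst$rec, iterations = 6)
  expect_true(all(diff(m2$history$loss) <= 1e-10))
})

test_that("prediction sums every reached node, matching a path-enumeration oracle", {
  m <- manual_tree()
  x1 <- tibble::tibble(q = 0L, r = 0L)
  expect_equal(predict_score(m, x1), 0.5 - 2.0 - 0.5)
  x2 <- tibble::tibble(q = 2L, r = 0L)
  expect_equal(predict_score(m, x2), 0.5 + 1.0)
  x3 <- tibble::tibble(q = 2L, r = 2L)
  expect_equal(predict_score(m, x3), 1.5)
  # agreement with the recursive oracle on random inputs, incl. a fitted model
  grid <- expand.grid(q = 0:2, r = 0:2)
  for (i in seq_len(nrow(grid))) {
    expect_equal(predict_score(m, tibble::as_tibble(grid[i, ])),
                 oracle_score(m, grid[i, ]))
  }
  inst <- random_recoded(20, 3, seed = 5)
  fm <- fit_adtree(inst$rec, iterations = 4)
  sheets <- random_sheets(25, colnames(inst$X), seed = 6)
  got <- predict_score(fm, sheets)
  want <- vapply(seq_len(nrow(sheets)), function(i) oracle_score(fm, sheets[i, ]),
                 numeric(1))
  expect_equal(got, want)
  used <- extract_items(fm)$item[1]
  expect_error(predict_score(fm, sheets[, setdiff(names(sheets), used)]), used)
})

test_that("scores are piecewise constant with breakpoints only at model thresholds", {
  inst <- random_recoded(24, 3, seed = 9)
  m <- fit_adtree(inst$rec, iterations = 3)
  x <- tibble::tibble(it1 = 1, it2 = 0, it3 = 2)
  thr <- sort(unique(m$splits$threshold[m$splits$item == "it1"]))
  for (v in c(0, 0.4, 1.2, 1.9, 2)) {
    x2 <- x
    x2$it1 <- v
    x3 <- x
    eps <- 0.04
    x3$it1 <- v + eps
    crossed <- any(thr > v & thr <= v + eps)
    if (!crossed) {
      expect_equal(predict_score(m, x2), predict_score(m, x3))
    }
  }
})

test_that("fitting is invariant to training record order", {
  inst <- random_recoded(18, 3, seed = 31)
  m1 <- fit_adtree(inst$rec, iterations = 4)
  perm <- withr::with_seed(8, sample.int(nrow(inst$rec)))
  m2 <- fit_adtree(inst$rec[perm, ], iterations = 4)
  expect_identical(m1$pred_nodes, m2$pred_nodes)
  expect_identical(m1$splits, m2$splits)
  expect_identical(m1$history, m2$history)
})

test_that("score classification follows the sign rule with amplitude as confidence", {
  cl <- classify_score(c(-3.2, 0.179, 0), band = 0.5)
  expect_equal(cl$diagnosis, c("autism", "non_spectrum", "non_spectrum"))
  expect_equal(cl$confidence, c(3.2, 0.179, 0))
  expect_equal(cl$low_confidence, c(FALSE, TRUE, TRUE))
  # label flips iff the score crosses zero
  s <- seq(-1, 1, by = 0.25)
  cl2 <- classify_score(s, band = 0.1)
  expect_equal(cl2$label, ifelse(s < 0, -1L, 1L))
  expect_error(classify_score(Inf), class = "adirshort_validation_error")
  expect_error(classify_score(0.1, band = -1), class = "adirshort_config_error")
})

test_that("extract_items reports distinct items with multiplicities", {
  m <- adirshort:::new_adtree(0.1, items = c("i12", "i48"), epsilon = 1)
  m <- adirshort:::adtree_add_split(m, 1L, "i12", 0.5, -0.1, 0.1)
  m <- adirshort:::adtree_add_split(m, 2L, "i12", 1.5, -0.2, 0.2)
  m <- adirshort:::adtree_add_split(m, 1L, "i48", 0.5, -0.3, 0.3)
  it <- extract_items(m)
  expect_equal(it$item, c("i12", "i48"))
  expect_equal(it$multiplicity, c(2L, 1L))
  root_only <- adirshort:::new_adtree(0.4, items = "a", epsilon = 1)
  expect_equal(nrow(extract_items(root_only)), 0)
})

test_that("model files round-trip with exactly reproduced scores", {
  f <- withr::local_tempfile(fileext = ".json")
  root_only <- fit_adtree(tibble::tibble(label = rep(1L, 3), a = 0:2),
                          iterations = 0)
  write_model(root_only, f)
  expect_equal(predict_score(read_model(f), tibble::tibble(a = 1L)),
               predict_score(root_only, tibble::tibble(a = 1L)))

  rec <- recode_cohort(small_cohort(seed = 13))
  m <- fit_adtree(rec, iterations = 10)
  write_model(m, f)
  m2 <- read_model(f)
  sheets <- random_sheets(100, item_cols(rec), seed = 14)
  expect_identical(predict_score(m, sheets), predict_score(m2, sheets))

  # truncated file is a parse error
  txt <- readLines(f)
  g <- withr::local_tempfile(fileext = ".json")
  writeLines(head(txt, length(txt) %/% 2), g)
  expect_error(read_model(g), class = "adirshort_parse_error")

  # missing child / non-finite value are parse errors naming the node path
  bad <- list(format_version = 1, model_type = "adtree", epsilon = 1,
              items = "a",
              root = list(value = 0.2, splits = list(
                list(split_id = 1, item = "a", threshold = 0.5,
                     lo = list(value = 0.1)))))
  jsonlite::write_json(bad, g, auto_unbox = TRUE)
  expect_error(read_model(g), "missing child")
  bad$root$splits[[1]]$hi <- list(value = "NaN")
  bad$root$splits[[1]]$lo <- list(value = 0.1)
  jsonlite::write_json(bad, g, auto_unbox = TRUE)
  expect_error(read_model(g), class = "adirshort_parse_error")
})
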