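test_that("raw answer recoding collapses severity 3 and zeroes exception codes", {
  expect_equal(recode_answer(c(0, 1, 2)), c(0L, 1L, 2L))
  expect_equal(recode_answer(3), 2L)
  expect_equal(recode_answer(c(7, 8, 9)), c(0L, 0L, 0L))
  # idempotent on its image
  codes <- c(0L, 1L, 2L, 3L, 7L, 8L, 9L)
  expect_equal(recode_answer(recode_answer(codes)), recode_answer(codes))
  expect_error(recode_answer(4, item = "q01", subject = "s1"),
               class = "adirshort_validation_error")
  expect_error(recode_answer(5), "allowed codes")
})

test_that("cohort recoding is elementwise with the autism = -1 sign convention", {
  sheets <- tibble::tibble(
    subject_id = c("a", "b"),
    diagnosis = c("autism", "non_spectrum"),
    i1 = c(0L, 2L), i2 = c(3L, 1L), i3 = c(9L, 7L)
  )
  rec <- recode_cohort(sheets)
  expect_equal(unname(as.matrix(rec[, c("i1", "i2", "i3")])),
               matrix(c(0L, 2L, 2L, 1L, 0L, 0L), nrow = 2))
  expect_equal(rec$label, c(-1L, 1L))
  expect_error(recode_cohort(sheets, retained = character()),
               class = "adirshort_validation_error")
})

test_that("unknown diagnoses are excluded with a warning, not silently dropped", {
  sheets <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    diagnosis = c("autism", "unknown", "non_spectrum"),
    i1 = c(1L, 1L, 1L)
  )
  expect_warning(rec <- recode_cohort(sheets), "unknown diagnosis")
  expect_equal(rec$subject_id, c("a", "c"))
})

test_that("a full-size imbalanced cohort recodes to the expected matrix shape", {
  labels <- c(rep("autism", 891), rep("non_spectrum", 75))
  sheets <- tibble::tibble(
    subject_id = as.character(seq_along(labels)),
    diagnosis = labels,
    i1 = rep(2L, length(labels)), i2 = rep(0L, length(labels))
  )
  rec <- recode_cohort(sheets)
  expect_equal(nrow(rec), 966)
  expect_equal(sum(rec$label), -891 + 75)
})

test_that("item exclusion uses a strict exception-code majority plus a config list", {
  sheets <- tibble::tibble(
    subject_id = as.character(1:100),
    diagnosis = "autism",
    heavy = c(rep(8L, 60), rep(0L, 40)),   # 60% exceptions -> excluded
    clean = rep(1L, 100),                  # none -> retained
    border = c(rep(9L, 50), rep(1L, 50)),  # exactly 50% -> retained
    special = rep(0L, 100)
  )
  excl <- identify_excluded_items(sheets)
  expect_setequal(excl, "heavy")
  excl2 <- identify_excluded_items(sheets, special_items = "special")
  expect_setequal(excl2, c("heavy", "special"))
  expect_error(identify_excluded_items(sheets, threshold = 0),
               class = "adirshort_config_error")
  # exclusion depends only on per-item marginals: permuting subjects is a no-op
  perm <- sheets[sample.int(nrow(sheets)), ]
  expect_setequal(identify_excluded_items(perm), excl)
})

test_that("domain totals sum recoded scores and are order-invariant", {
  items <- adir_items()
  map <- domain_map(items)
  zero <- tibble::as_tibble(setNames(as.list(rep(0L, 93)), items$abbreviation))
  ds0 <- domain_scores(zero, map)
  expect_equal(c(ds0$social, ds0$communication, ds0$rrb), c(0L, 0L, 0L))

  small_map <- list(social = paste0("s", 1:5), communication = "c1", rrb = "r1")
  sheet <- tibble::as_tibble(setNames(as.list(c(rep(2L, 5), 1L, 0L)),
                                      c(paste0("s", 1:5), "c1", "r1")))
  expect_equal(domain_scores(sheet, small_map)$social, 10L)

  # the generator writes exact totals; domain_scores must recover them
  scores <- c(allocate_domain_total(9, 15, seed = 4),
              allocate_domain_total(7, 13, seed = 5),
              allocate_domain_total(2, 8, seed = 6))
  algo_items <- unlist(map, use.names = FALSE)
  sheet2 <- tibble::as_tibble(setNames(as.list(scores), algo_items))
  ds2 <- domain_scores(sheet2, map)
  expect_equal(c(ds2$social, ds2$communication, ds2$rrb), c(9L, 7L, 2L))
  shuffled <- sheet2[, sample(names(sheet2))]
  expect_equal(domain_scores(shuffled, map), ds2)
})

test_that("the diagnostic algorithm requires all three domain cutoffs to be met", {
  ds <- tibble::tibble(
    social = c(10L, 10L, 9L),
    communication = c(8L, 7L, 20L),
    rrb = c(3L, 3L, 20L)
  )
  expect_equal(adir_algorithm_classify(ds, verbal = c(TRUE, FALSE, TRUE)),
               c("autism", "autism", "non_spectrum"))
  # verbal subject at the nonverbal communication cutoff does not qualify
  expect_equal(adir_algorithm_classify(
    tibble::tibble(social = 10L, communication = 7L, rrb = 3L), verbal = TRUE),
    "non_spectrum")
})

test_that("the diagnostic algorithm is monotone in every domain total", {
  withr::with_seed(3, {
    for (i in 1:200) {
      ds <- tibble::tibble(social = sample(0:30, 1),
                           communication = sample(0:26, 1),
                           rrb = sample(0:16, 1))
      verbal <- sample(c(TRUE, FALSE), 1)
      base <- adir_algorithm_classify(ds, verbal)
      bumped <- ds
      dom <- sample(names(ds), 1)
      bumped[[dom]] <- bumped[[dom]] + 1L
      up <- adir_algorithm_classify(bumped, verbal)
      if (base == "autism") expect_equal(up, "autism")
    }
  })
})

test_that("age filtering uses a half-open interval in months", {
  sheets <- tibble::tibble(subject_id = letters[1:4],
                           age_months = c(59L, 60L, 202L, 204L))
  expect_equal(filter_by_age(sheets, 5, 17)$subject_id, c("b", "c"))
  expect_equal(nrow(filter_by_age(sheets[0, ], 5, 17)), 0)
  young <- tibble::tibble(subject_id = c("x", "y", "z"),
                          age_months = c(13L, 48L, 60L))
  expect_equal(filter_by_age(young, max_years = 5)$subject_id, c("x", "y"))
})

test_that("answer sheets and instrument definitions round-trip through files", {
  co <- small_cohort(seed = 2, n_cases = 8, n_controls = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_answer_sheets(co, f)
  back <- read_answer_sheets(f)
  expect_equal(as.data.frame(back), as.data.frame(co))

  g <- withr::local_tempfile(fileext = ".yml")
  write_instrument(adir_items(), g)
  items2 <- read_instrument(g)
  expect_equal(as.data.frame(items2), as.data.frame(adir_items()))
})
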