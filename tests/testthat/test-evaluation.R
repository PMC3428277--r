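test_that("confusion tables cross-tabulate with autism as the positive class", {
  ct <- confusion_table(c(-1, -1, 1, 1), c(-1, 1, 1, -1))
  expect_equal(as.list(ct), list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  # string labels are accepted
  ct2 <- confusion_table(c("autism", "non_spectrum"), c("autism", "non_spectrum"))
  expect_equal(c(ct2$tp, ct2$tn), c(1L, 1L))
  truth <- c(rep(-1, 891), rep(1, 75))
  ct3 <- confusion_table(truth, truth)
  expect_equal(c(ct3$tp, ct3$tn, ct3$fp, ct3$fn), c(891L, 75L, 0L, 0L))
  expect_error(confusion_table(numeric(0), numeric(0)),
               class = "adirshort_validation_error")
  expect_error(confusion_table(c(-1, 1), -1), "equal length")
})

test_that("metric arithmetic reproduces count-derived rates at printed precision", {
  m <- metrics(tibble::tibble(tp = 891, fn = 0, fp = 1, tn = 74))
  expect_equal(m$tpr, 1.0)
  expect_equal(round(m$fpr, 3), 0.013)
  expect_equal(m$accuracy, 965 / 966)
  fm <- format_metrics(m)
  expect_equal(fm$fpr, "0.013")
  expect_equal(fm$accuracy, "99.90%")

  cases_only <- metrics(tibble::tibble(tp = 321, fn = 1, fp = 0, tn = 0))
  expect_equal(cases_only$sensitivity, 321 / 322)
  expect_true(is.na(cases_only$fpr))
  expect_equal(format_metrics(cases_only)$fpr, "NA")

  controls_only <- metrics(tibble::tibble(tp = 0, fn = 0, fp = 62, tn = 938))
  expect_equal(controls_only$specificity, 0.938)
  expect_true(is.na(controls_only$sensitivity))
})

test_that("stratified folds partition the data with near-equal sizes per class", {
  rec <- tibble::tibble(
    subject_id = as.character(1:20),
    label = rep(c(-1L, 1L), each = 10),
    it1 = rep(0:2, length.out = 20),
    it2 = rep(c(0L, 2L), 10)
  )
  cv <- kfold_cv(rec, stump_learner(), k = 10, seed = 3)
  expect_setequal(cv$predictions$subject_id, rec$subject_id)
  expect_equal(nrow(cv$predictions), 20)  # each record predicted exactly once
  sizes <- table(cv$predictions$fold)
  expect_true(all(sizes == 2))
  # fold sizes per class differ by <= 1
  joined <- dplyr::left_join(cv$predictions,
                             tibble::tibble(subject_id = rec$subject_id,
                                            label = rec$label),
                             by = "subject_id")
  per_class <- table(joined$fold, joined$label)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x)) <= 1)))
})

test_that("a constant majority-class predictor attains the closed-form accuracy", {
  rec <- tibble::tibble(
    subject_id = as.character(1:966),
    label = c(rep(-1L, 891), rep(1L, 75)),
    it1 = 0L # no split possible: the stump degenerates to the majority class
  )
  cv <- kfold_cv(rec, stump_learner(), k = 10, seed = 5)
  expect_equal(cv$metrics$accuracy, 891 / 966)
  expect_equal(cv$metrics$tpr, 1)
  expect_equal(cv$metrics$fpr, 1)
})

test_that("cross-validation is deterministic given the seed", {
  rec <- recode_cohort(small_cohort(seed = 41, n_cases = 60, n_controls = 20))
  cv1 <- kfold_cv(rec, adtree_learner(iterations = 3), k = 5, seed = 9)
  cv2 <- kfold_cv(rec, adtree_learner(iterations = 3), k = 5, seed = 9)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$metrics, cv2$metrics)
})

test_that("a class smaller than k falls back to unstratified folds with a warning", {
  rec <- tibble::tibble(label = c(rep(-1L, 17), rep(1L, 3)),
                        it1 = rep(0:1, 10))
  expect_warning(cv <- kfold_cv(rec, stump_learner(), k = 5, seed = 1),
                 "unstratified")
  expect_equal(nrow(cv$predictions), 20)
})

test_that("classifier comparison collects CV rows and appends external rows verbatim", {
  rec <- recode_cohort(small_cohort(seed = 51, n_cases = 60, n_controls = 20))
  learners <- list(adtree_learner(iterations = 3), stump_learner(), oner_learner())
  ext <- tibble::tibble(classifier = "ADTree (published)",
                        fpr = 0.013, tpr = 1.000, accuracy = 0.999)
  cmp <- compare_classifiers(rec, learners, external = ext, k = 5, seed = 2)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$fpr >= 0 & cmp$fpr <= 1))
  expect_true(all(cmp$tpr >= 0 & cmp$tpr <= 1))
  pub <- cmp[cmp$source == "external", ]
  expect_equal(c(pub$fpr, pub$tpr, pub$accuracy), c(0.013, 1.000, 0.999))

  # external rows only (no learners) still yields a full table
  many <- tibble::tibble(classifier = paste0("alg", 1:15),
                         fpr = seq(0.01, 0.15, by = 0.01),
                         tpr = rep(0.99, 15), accuracy = rep(0.98, 15))
  cmp2 <- compare_classifiers(rec, list(), external = many)
  expect_equal(nrow(cmp2), 15)
  expect_s3_class(autoplot(cmp2), "ggplot")

  # row order is the only thing learner order can change
  cmp3 <- compare_classifiers(rec, rev(learners), external = ext, k = 5, seed = 2)
  expect_equal(dplyr::arrange(as.data.frame(cmp3), classifier),
               dplyr::arrange(as.data.frame(cmp), classifier))
})

test_that("score profiles pair scores with ages and preserve flags", {
  co <- small_cohort(seed = 61, n_cases = 20, n_controls = 8)
  root_only <- fit_adtree(recode_cohort(co)[1:5, ], iterations = 0)
  prof <- score_profile(root_only, co[1:3, ])
  expect_equal(nrow(prof), 3)
  expect_equal(length(unique(prof$score)), 1)
  expect_equal(prof$age_years, co$age_months[1:3] / 12)

  thirteen_months <- co[1, ]
  thirteen_months$age_months <- 13L
  prof13 <- score_profile(root_only, thirteen_months)
  expect_equal(prof13$age_years, 13 / 12, tolerance = 1e-12)
  expect_equal(round(prof13$age_years, 2), 1.08)
})

test_that("true-label fits concentrate score mass away from zero versus permuted labels", {
  co <- small_cohort(seed = 71)
  rec <- recode_cohort(co)
  m_true <- fit_adtree(rec, iterations = 10)
  rec_perm <- rec
  rec_perm$label <- withr::with_seed(4, sample(rec$label))
  m_perm <- fit_adtree(rec_perm, iterations = 10)
  med_true <- median(abs(predict_score(m_true, rec)))
  med_perm <- median(abs(predict_score(m_perm, rec_perm)))
  expect_gt(med_true, med_perm)
})

test_that("cv tidiers expose per-fold and pooled metrics", {
  rec <- recode_cohort(small_cohort(seed = 81, n_cases = 40, n_controls = 20))
  cv <- kfold_cv(rec, adtree_learner(iterations = 2), k = 4, seed = 1)
  td <- tidy(cv)
  expect_equal(nrow(td), 4)
  gl <- glance(cv)
  expect_equal(gl$learner, "ADTree")
  expect_equal(gl$n, nrow(rec))
})
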