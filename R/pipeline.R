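# File-based pipeline commands: simulate / train / evaluate / screen.
# Each command writes its artifacts plus a provenance sidecar (seed, config
# digest, stage-by-stage record counts) so every run is reproducible from
# its outputs. A thin command-line dispatcher over these functions ships in
# inst/cli/adirshort.R.

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 13L + offset) %% .Machine$integer.max)
}

write_provenance <- function(path, command, seed, digest, counts = list(),
                             params = list()) {
  yaml::write_yaml(list(command = command, seed = seed, config_digest = digest,
                        counts = counts, params = params), path)
  invisible(path)
}

#' Simulate the study's data files
#'
#' Generates the planted-signal case/control cohort, per-item resampled
#' controls drawn from the cohort's observed control pool, and near-cutoff
#' simulated controls, writing all three as delimited answer-sheet files
#' plus a provenance sidecar. All randomness derives from the single
#' `seed`, split deterministically per stage; re-running with the same
#' inputs reproduces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_cfg A [cohort_config()].
#' @param near_cfg A [near_cutoff_config()].
#' @param n_resampled Number of pool-resampled control sheets.
#' @param seed Top-level integer seed.
#' @return Invisibly, a named list of written file paths.
#' @export
cmd_simulate <- function(out_dir, cohort_cfg = cohort_config(),
                         near_cfg = near_cutoff_config(),
                         n_resampled = 1000L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cohort_cfg, seed = stage_seed(seed, 1L))
  pool <- build_control_pool(cohort)
  resampled <- resample_controls(pool, n = n_resampled,
                                 seed = stage_seed(seed, 2L))
  near <- simulate_near_cutoff_controls(near_cfg, seed = stage_seed(seed, 3L))
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    resampled_controls = file.path(out_dir, "resampled_controls.csv"),
    near_cutoff_controls = file.path(out_dir, "near_cutoff_controls.csv"),
    provenance = file.path(out_dir, "simulate_provenance.yml")
  )
  write_answer_sheets(cohort, paths$cohort)
  write_answer_sheets(resampled, paths$resampled_controls)
  write_answer_sheets(near, paths$near_cutoff_controls)
  write_provenance(
    paths$provenance, "simulate", seed,
    digest = rlang::hash(list(cohort_cfg, near_cfg, n_resampled)),
    counts = list(cohort = nrow(cohort), resampled = nrow(resampled),
                  near_cutoff = nrow(near),
                  pool_controls = pool$n_controls),
    params = list(n_cases = cohort_cfg$n_cases,
                  n_controls = cohort_cfg$n_controls,
                  n_resampled = n_resampled, near_n = near_cfg$n,
                  delta = near_cfg$delta)
  )
  invisible(paths)
}

prepare_training_data <- function(sheets, age_min, age_max,
                                  exception_threshold, special_items) {
  n_read <- nrow(sheets)
  excluded <- identify_excluded_items(sheets, threshold = exception_threshold,
                                      special_items = special_items)
  retained <- setdiff(item_cols(sheets), excluded)
  aged <- filter_by_age(sheets, age_min, age_max)
  rec <- recode_cohort(aged, retained = retained)
  list(recoded = rec, excluded = excluded, retained = retained,
       counts = list(read = n_read, excluded_items = length(excluded),
                     after_age_filter = nrow(aged), recoded = nrow(rec)))
}

#' Train an ADTree from an answer-sheet file
#'
#' Applies exception-code item exclusion, the default 5-17-year age window
#' and recoding, fits the alternating decision tree, and writes the model
#' file, a per-iteration training log (chosen rule, Z, exponential loss),
#' the excluded-item list and a provenance sidecar.
#'
#' @param cohort_file Path to an answer-sheet file.
#' @param out_dir Output directory.
#' @param iterations,epsilon ADTree training parameters.
#' @param age_min,age_max Age window in years (half-open; `NULL` disables a
#'   bound).
#' @param exception_threshold Exception-code exclusion threshold.
#' @param special_items Abbreviations force-excluded from training.
#' @param seed Seed recorded in provenance (training itself is
#'   deterministic).
#' @return Invisibly, a list with the fitted `model` and written `paths`.
#' @export
cmd_train <- function(cohort_file, out_dir, iterations = 10L, epsilon = 1,
                      age_min = 5, age_max = 17, exception_threshold = 0.5,
                      special_items = character(), seed = 1L) {
  if (!file.exists(cohort_file)) {
    abort(sprintf("Input file does not exist: %s", cohort_file),
          class = "adirshort_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheets <- read_answer_sheets(cohort_file)
  prep <- prepare_training_data(sheets, age_min, age_max,
                                exception_threshold, special_items)
  model <- fit_adtree(prep$recoded, iterations = iterations, epsilon = epsilon)
  paths <- list(
    model = file.path(out_dir, "model.json"),
    training_log = file.path(out_dir, "training_log.csv"),
    excluded_items = file.path(out_dir, "excluded_items.txt"),
    provenance = file.path(out_dir, "train_provenance.yml")
  )
  write_model(model, paths$model)
  readr::write_csv(tidy(model), paths$training_log)
  writeLines(prep$excluded, paths$excluded_items)
  write_provenance(
    paths$provenance, "train", seed,
    digest = rlang::hash(list(iterations, epsilon, age_min, age_max,
                              exception_threshold, special_items)),
    counts = c(prep$counts, list(splitters = nrow(model$splits))),
    params = list(iterations = iterations, epsilon = epsilon,
                  age_min = age_min, age_max = age_max)
  )
  invisible(list(model = model, excluded = prep$excluded, paths = paths))
}

#' Evaluate classifiers on a cohort file
#'
#' Runs stratified k-fold cross-validation of the ADTree and the two
#' baselines inside the training age window, appends any externally
#' computed comparison rows verbatim, evaluates a full-data ADTree on an
#' optional held-out file and on the cohort's under-`under_age` subgroup,
#' and writes the metrics report, comparison table and score-vs-age
#' profile.
#'
#' @param cohort_file Path to the training answer-sheet file.
#' @param out_dir Output directory.
#' @param k Cross-validation folds.
#' @param iterations,epsilon,band ADTree and confidence parameters.
#' @param age_min,age_max Training age window in years.
#' @param under_age Upper bound (years) of the young-children subgroup
#'   report.
#' @param external Optional tibble (or CSV path) of precomputed rows
#'   `classifier, fpr, tpr, accuracy` appended to the comparison.
#' @param holdout_file Optional held-out answer-sheet file scored by the
#'   full-data model.
#' @param exception_threshold,special_items Item-exclusion settings.
#' @param seed Top-level seed (fold shuffling).
#' @return Invisibly, a list with the comparison tibble, reports and
#'   written paths.
#' @export
cmd_evaluate <- function(cohort_file, out_dir, k = 10L, iterations = 10L,
                         epsilon = 1, band = 0.5, age_min = 5, age_max = 17,
                         under_age = 5, external = NULL, holdout_file = NULL,
                         exception_threshold = 0.5,
                         special_items = character(), seed = 1L) {
  if (!file.exists(cohort_file)) {
    abort(sprintf("Input file does not exist: %s", cohort_file),
          class = "adirshort_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheets <- read_answer_sheets(cohort_file)
  prep <- prepare_training_data(sheets, age_min, age_max,
                                exception_threshold, special_items)
  if (is.character(external)) {
    external <- readr::read_csv(external, show_col_types = FALSE)
  }
  learners <- list(adtree_learner(iterations, epsilon), stump_learner(),
                   oner_learner())
  comparison <- compare_classifiers(prep$recoded, learners, external = external,
                                    k = k, seed = stage_seed(seed, 4L))
  model <- fit_adtree(prep$recoded, iterations = iterations, epsilon = epsilon)

  report <- list(
    cv = as.list(glance(kfold_cv(prep$recoded, learners[[1]], k = k,
                                 seed = stage_seed(seed, 4L))))
  )

  if (!is.null(holdout_file)) {
    held <- read_answer_sheets(holdout_file)
    rec_h <- recode_cohort(held, retained = prep$retained)
    s <- predict_score(model, rec_h)
    pred <- ifelse(s < 0, LABEL_AUTISM, LABEL_NON_SPECTRUM)
    report$holdout <- as.list(metrics(confusion_table(rec_h$label, pred)))
  }

  young <- filter_by_age(sheets, min_years = NULL, max_years = under_age)
  if (nrow(young) > 0) {
    rec_y <- recode_cohort(young, retained = prep$retained)
    s <- predict_score(model, rec_y)
    pred <- ifelse(s < 0, LABEL_AUTISM, LABEL_NON_SPECTRUM)
    report$under_age <- as.list(metrics(confusion_table(rec_y$label, pred)))
  }

  profile <- score_profile(model, filter_by_age(sheets, age_min, NULL)[
    filter_by_age(sheets, age_min, NULL)$diagnosis != "unknown", ], band = band)

  paths <- list(
    comparison = file.path(out_dir, "comparison.csv"),
    score_profile = file.path(out_dir, "score_profile.csv"),
    report = file.path(out_dir, "evaluation_report.yml"),
    provenance = file.path(out_dir, "evaluate_provenance.yml")
  )
  readr::write_csv(comparison, paths$comparison)
  readr::write_csv(profile, paths$score_profile)
  yaml::write_yaml(report, paths$report)
  write_provenance(
    paths$provenance, "evaluate", seed,
    digest = rlang::hash(list(k, iterations, epsilon, band, age_min, age_max)),
    counts = prep$counts,
    params = list(k = k, iterations = iterations, band = band)
  )
  invisible(list(comparison = comparison, report = report, profile = profile,
                 model = model, paths = paths))
}

#' Screen answer sheets with a stored model
#'
#' Scores each subject in an answers file with a model file, writing one
#' row per subject with the classification, signed score, confidence and
#' low-confidence flag (borderline scores warranting closer inspection and
#' further behavioural assessment).
#'
#' @param model_file Path to a model written by [write_model()].
#' @param answers_file Path to an answer-sheet file containing every item
#'   the model references.
#' @param out_file Output CSV path.
#' @param band Low-confidence band half-width.
#' @return Invisibly, the per-subject results tibble.
#' @export
cmd_screen <- function(model_file, answers_file, out_file, band = 0.5) {
  for (f in c(model_file, answers_file)) {
    if (!file.exists(f)) {
      abort(sprintf("Input file does not exist: %s", f),
            class = "adirshort_config_error")
    }
  }
  model <- read_model(model_file)
  sheets <- read_answer_sheets(answers_file)
  rec <- sheets
  for (it in item_cols(sheets)) {
    rec[[it]] <- recode_answer(sheets[[it]], item = it,
                               subject = sheets$subject_id)
  }
  s <- predict_score(model, rec)
  cl <- classify_score(s, band = band)
  out <- dplyr::bind_cols(tibble(subject_id = sheets$subject_id), cl)
  readr::write_csv(out, out_file)
  invisible(out)
}
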