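# Synthetic cohorts standing in for the access-restricted repositories:
# a planted-signal case/control generator shaped like the training data
# (sample sizes, age quartiles, exception codes), plus the two control
# simulators used for specificity experiments — per-item resampling from an
# observed control pool, and constrained sheets whose three domain totals
# sit just below the diagnostic cutoffs.

#' Configuration for the planted-signal cohort generator
#'
#' Defaults emulate the classifier-construction cohort: 891 autism cases
#' and 75 non-spectrum controls aged 5-17 with the reported age quartiles,
#' a seven-item informative subset carrying the class separation, a shared
#' background answer distribution on all other items, occasional exception
#' codes, and two designated items dominated by exception codes so that
#' data-driven item exclusion is exercised end to end.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param informative_items Item abbreviations carrying the planted signal.
#' @param p_high_case,p_high_control Probability that an informative item
#'   scores 2 for a case / control.
#' @param p_mid_case,p_mid_control Conditional probability that an
#'   informative item scores 1 (rather than 0) when it does not score 2.
#'   The class-specific defaults make the planted signal ordinal — severity
#'   shifts the whole 0/1/2 distribution, as it does for genuinely
#'   discriminative instrument items — so both score thresholds of an
#'   informative item separate the classes.
#' @param background_probs Raw-code distribution (codes 0,1,2,3) for
#'   uninformative items, identical in both classes.
#' @param exception_rate Per-answer probability of replacement by an
#'   exception code (7, 8 or 9).
#' @param forced_exclusion_items Items whose answers are exception codes
#'   with probability `forced_exception_rate` (> 0.5), so they end up
#'   excluded by [identify_excluded_items()].
#' @param forced_exception_rate Exception probability on forced items.
#' @param age_quartiles_cases,age_quartiles_controls Target age quartiles
#'   (Q1, median, Q3) in years.
#' @param age_range Half-open age window in years for the generated cohort.
#' @param verbal_fraction Probability a subject is verbal.
#' @param items Instrument table ([adir_items()]).
#' @param cutoffs Diagnostic cutoffs ([adir_cutoffs()]).
#' @param map Item-to-domain mapping ([domain_map()]).
#' @param max_batches Resampling bound before the generator gives up on
#'   satisfying the diagnostic constraints.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 891L, n_controls = 75L,
                          informative_items = published_subset,
                          p_high_case = 0.9, p_high_control = 0.05,
                          p_mid_case = 0.7, p_mid_control = 0.25,
                          background_probs = c(`0` = 0.55, `1` = 0.25,
                                               `2` = 0.15, `3` = 0.05),
                          exception_rate = 0.02,
                          forced_exclusion_items = c("q92", "q93"),
                          forced_exception_rate = 0.75,
                          age_quartiles_cases = c(6.44, 8.06, 10.84),
                          age_quartiles_controls = c(6.38, 9.24, 11.88),
                          age_range = c(5, 17),
                          verbal_fraction = 0.8,
                          items = adir_items(),
                          cutoffs = adir_cutoffs(),
                          map = domain_map(items),
                          max_batches = 50L) {
  probs <- c(p_high_case, p_high_control, p_mid_case, p_mid_control,
             exception_rate, forced_exception_rate, verbal_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "adirshort_config_error")
  }
  if (n_cases < 0 || n_controls < 0) {
    abort("Cohort sizes must be non-negative.", class = "adirshort_config_error")
  }
  for (q in list(age_quartiles_cases, age_quartiles_controls)) {
    if (any(diff(q) <= 0)) {
      abort("Age quartile targets must be increasing.", class = "adirshort_config_error")
    }
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         informative_items = informative_items,
         p_high_case = p_high_case, p_high_control = p_high_control,
         p_mid_case = p_mid_case, p_mid_control = p_mid_control,
         background_probs = background_probs,
         exception_rate = exception_rate,
         forced_exclusion_items = forced_exclusion_items,
         forced_exception_rate = forced_exception_rate,
         age_quartiles_cases = age_quartiles_cases,
         age_quartiles_controls = age_quartiles_controls,
         age_range = age_range, verbal_fraction = verbal_fraction,
         items = items, cutoffs = cutoffs, map = map,
         max_batches = max_batches),
    class = "cohort_config"
  )
}

# Log-normal age sampler fitted to (Q1, median, Q3) targets in years,
# truncated to the configured window by rejection; returns integer months.
sample_ages_months <- function(n, quartiles, range_years) {
  if (n == 0) return(integer(0))
  mu <- log(quartiles[2])
  sigma <- mean(c(log(quartiles[3] / quartiles[2]),
                  log(quartiles[2] / quartiles[1]))) / qnorm(0.75)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(2 * n, mu, sigma)
    draw <- draw[draw >= range_years[1] & draw < range_years[2]]
    out <- c(out, draw)
  }
  months <- as.integer(round(out[seq_len(n)] * 12))
  pmin(pmax(months, as.integer(ceiling(range_years[1] * 12))),
       as.integer(range_years[2] * 12) - 1L)
}

# One batch of raw answer matrices (n x 93) for a class.
sample_raw_batch <- function(n, cfg, p_high, p_mid) {
  abbr <- cfg$items$abbreviation
  m <- length(abbr)
  informative <- abbr %in% cfg$informative_items
  forced <- abbr %in% cfg$forced_exclusion_items
  raw <- matrix(0L, n, m, dimnames = list(NULL, abbr))
  n_bg <- sum(!informative)
  if (n_bg > 0) {
    codes <- as.integer(names(cfg$background_probs))
    raw[, !informative] <- sample(codes, n * n_bg, replace = TRUE,
                                  prob = cfg$background_probs)
  }
  if (any(informative)) {
    n_inf <- sum(informative)
    u <- matrix(runif(n * n_inf), n, n_inf)
    sc <- matrix(0L, n, n_inf)
    sc[u < p_high] <- 2L
    mid <- u >= p_high & u < p_high + (1 - p_high) * p_mid
    sc[mid] <- 1L
    raw[, informative] <- sc
  }
  # Exception-code injection (forced-exclusion items at a majority rate).
  rate <- matrix(cfg$exception_rate, n, m, byrow = TRUE)
  rate[, forced] <- cfg$forced_exception_rate
  hit <- matrix(runif(n * m), n, m) < rate
  if (any(hit)) {
    raw[hit] <- sample(EXCEPTION_CODES, sum(hit), replace = TRUE)
  }
  raw
}

raw_matrix_classify <- function(raw, verbal, cfg) {
  rec <- apply(raw, 2, recode_answer)
  if (is.null(dim(rec))) rec <- matrix(rec, nrow = nrow(raw),
                                       dimnames = dimnames(raw))
  ds <- tibble(
    social = as.integer(rowSums(rec[, cfg$map$social, drop = FALSE])),
    communication = as.integer(rowSums(rec[, cfg$map$communication, drop = FALSE])),
    rrb = as.integer(rowSums(rec[, cfg$map$rrb, drop = FALSE]))
  )
  adir_algorithm_classify(ds, verbal, cfg$cutoffs)
}

failing_domains <- function(raw, verbal, cfg) {
  rec <- apply(raw, 2, recode_answer)
  ds <- tibble(
    social = rowSums(rec[, cfg$map$social, drop = FALSE]),
    communication = rowSums(rec[, cfg$map$communication, drop = FALSE]),
    rrb = rowSums(rec[, cfg$map$rrb, drop = FALSE])
  )
  comm_cut <- ifelse(verbal, cfg$cutoffs$comm_cut_verbal, cfg$cutoffs$comm_cut_nonverbal)
  fails <- c(
    social = mean(ds$social < cfg$cutoffs$social_cut),
    communication = mean(ds$communication < comm_cut),
    rrb = mean(ds$rrb < cfg$cutoffs$rrb_cut)
  )
  names(which.max(fails))
}

sample_class_sheets <- function(n, cfg, p_high, p_mid, want, prefix) {
  abbr <- cfg$items$abbreviation
  kept_raw <- matrix(0L, 0, length(abbr), dimnames = list(NULL, abbr))
  kept_verbal <- logical(0)
  batches <- 0L
  while (nrow(kept_raw) < n) {
    batches <- batches + 1L
    if (batches > cfg$max_batches) {
      raw <- sample_raw_batch(n, cfg, p_high, p_mid)
      verbal <- runif(n) < cfg$verbal_fraction
      abort(sprintf(
        "Could not generate %d '%s' sheets within %d batches; constraint most often violated in the %s domain.",
        n, want, cfg$max_batches, failing_domains(raw, verbal, cfg)),
        class = "adirshort_config_error")
    }
    need <- n - nrow(kept_raw)
    draw_n <- max(need * 2L, 8L)
    raw <- sample_raw_batch(draw_n, cfg, p_high, p_mid)
    verbal <- runif(draw_n) < cfg$verbal_fraction
    ok <- raw_matrix_classify(raw, verbal, cfg) == want
    kept_raw <- rbind(kept_raw, raw[ok, , drop = FALSE])
    kept_verbal <- c(kept_verbal, verbal[ok])
  }
  kept_raw <- kept_raw[seq_len(n), , drop = FALSE]
  kept_verbal <- kept_verbal[seq_len(n)]
  quartiles <- if (want == "autism") cfg$age_quartiles_cases else cfg$age_quartiles_controls
  out <- tibble(
    subject_id = sprintf("%s_%04d", prefix, seq_len(n)),
    age_months = sample_ages_months(n, quartiles, cfg$age_range),
    verbal = kept_verbal,
    diagnosis = if (want == "autism") "autism" else "non_spectrum"
  )
  dplyr::bind_cols(out, as_tibble(as.data.frame(kept_raw)))
}

#' Generate a planted-signal case/control cohort
#'
#' Draws `n_cases` autism and `n_controls` non-spectrum answer sheets under
#' the configuration's planted-signal model, resampling each batch until
#' every case satisfies — and every control fails — the ADI-R domain-cutoff
#' algorithm under the configured mapping, so the generated labels agree
#' with the instrument's own algorithm by construction.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return Answer-sheet tibble: `subject_id`, `age_months`, `verbal`,
#'   `diagnosis`, then one raw-code column per item.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_cases = 30, n_controls = 10), seed = 1)
#' dplyr::count(cohort, diagnosis)
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  withr::with_seed(seed, {
    cases <- sample_class_sheets(cfg$n_cases, cfg, cfg$p_high_case,
                                 cfg$p_mid_case, "autism", "case")
    controls <- sample_class_sheets(cfg$n_controls, cfg, cfg$p_high_control,
                                    cfg$p_mid_control, "non_spectrum", "ctrl")
    bind_rows(cases, controls)
  })
}

#' Build a per-item control answer pool
#'
#' Collects, for every item, the multiset of raw answers observed among
#' non-spectrum sheets; [resample_controls()] draws from these multisets.
#'
#' @param sheets Answer-sheet tibble containing at least one non-spectrum
#'   subject.
#' @return Object of class `control_pool`: per-item answer vectors plus the
#'   underlying control rows (for whole-row resampling).
#' @export
build_control_pool <- function(sheets) {
  controls <- sheets[sheets$diagnosis == "non_spectrum", , drop = FALSE]
  if (nrow(controls) == 0) {
    abort("No non-spectrum sheets: cannot build a control pool.",
          class = "adirshort_validation_error")
  }
  items <- item_cols(controls)
  pool <- lapply(items, function(it) as.integer(controls[[it]]))
  names(pool) <- items
  structure(list(answers = pool, sheets = controls[, items, drop = FALSE],
                 n_controls = nrow(controls)),
            class = "control_pool")
}

#' Resample simulated controls from an observed pool
#'
#' Builds `n` artificial control sheets. In the default per-item mode each
#' item is sampled independently, uniformly with replacement, from that
#' item's observed answer multiset, so the simulated sheets share the
#' pool's marginal score distributions. Whole-row mode resamples complete
#' observed sheets instead (a sensitivity-analysis option that preserves
#' inter-item correlation).
#'
#' @param pool A [build_control_pool()] result.
#' @param n Number of sheets (default 1000); `n <= 0` yields an empty
#'   tibble.
#' @param seed Integer seed.
#' @param mode `"per_item"` (default) or `"whole_row"`.
#' @return Answer-sheet tibble with `diagnosis = "non_spectrum"`.
#' @export
resample_controls <- function(pool, n = 1000L, seed = 1L,
                              mode = c("per_item", "whole_row")) {
  mode <- match.arg(mode)
  items <- names(pool$answers)
  if (n <= 0) {
    empty <- c(list(subject_id = character(), diagnosis = character()),
               setNames(rep(list(integer()), length(items)), items))
    return(as_tibble(empty))
  }
  withr::with_seed(seed, {
    if (mode == "per_item") {
      cols <- lapply(pool$answers, function(v) sample(v, n, replace = TRUE))
    } else {
      rows <- sample.int(nrow(pool$sheets), n, replace = TRUE)
      cols <- lapply(items, function(it) pool$sheets[[it]][rows])
      names(cols) <- items
    }
  })
  dplyr::bind_cols(
    tibble(subject_id = sprintf("sim_pool_%04d", seq_len(n)),
           diagnosis = "non_spectrum"),
    as_tibble(cols)
  )
}

# Composition-count table: counts[t+1, s+1] = number of length-s sequences
# of integers in 0..max_score summing to t.
composition_counts <- function(m, max_total, max_score = 2L) {
  counts <- matrix(0, max_total + 1L, m + 1L)
  counts[1, 1] <- 1
  for (s in seq_len(m)) {
    for (t in 0:max_total) {
      vmax <- min(max_score, t)
      counts[t + 1L, s + 1L] <- sum(counts[(t - (0:vmax)) + 1L, s])
    }
  }
  counts
}

# Vectorised uniform allocation of each target total across m items with
# per-item scores 0..max_score; exact sequential sampling from the
# composition counts.
allocate_totals <- function(totals, m, max_score = 2L) {
  if (any(totals < 0 | totals > max_score * m)) {
    abort(sprintf("Infeasible domain total: must lie in [0, %d] for %d item(s).",
                  max_score * m, m), class = "adirshort_config_error")
  }
  counts <- composition_counts(m, max(max_score * m, max(totals, 0)), max_score)
  n <- length(totals)
  out <- matrix(0L, n, m)
  remaining <- as.integer(totals)
  for (i in seq_len(m)) {
    slots_left <- m - i
    for (t in sort(unique(remaining))) {
      sel <- which(remaining == t)
      vmax <- min(max_score, t)
      p <- counts[(t - (0:vmax)) + 1L, slots_left + 1L]
      if (length(p) == 1) {
        draw <- rep(0L, length(sel))
      } else {
        draw <- sample(0:vmax, length(sel), replace = TRUE, prob = p)
      }
      out[sel, i] <- draw
    }
    remaining <- remaining - out[, i]
  }
  out
}

#' Allocate a domain total across items uniformly
#'
#' Draws item scores in \{0, ..., `max_score`\} summing exactly to `total`,
#' uniformly over all such compositions (exact sequential sampling from
#' composition counts, not rejection).
#'
#' @param total Target domain total, `0 <= total <= max_score * m`.
#' @param m Number of items in the domain.
#' @param seed Integer seed.
#' @param max_score Per-item maximum (default 2).
#' @return Integer vector of `m` scores summing to `total`.
#' @examples
#' allocate_domain_total(3, 3, seed = 1)
#' @export
allocate_domain_total <- function(total, m, seed = 1L, max_score = 2L) {
  withr::with_seed(seed, as.integer(allocate_totals(total, m, max_score)[1, ]))
}

#' Configuration for the near-cutoff control simulator
#'
#' @param n Number of simulated sheets (default 1000).
#' @param cutoffs Diagnostic cutoffs ([adir_cutoffs()]).
#' @param delta Margin below each cutoff: domain targets are drawn
#'   uniformly from `[max(0, cutoff - delta), cutoff - 1]` (default 3).
#' @param items,map Instrument and item-to-domain mapping.
#' @param background_probs Raw-code distribution for items outside the
#'   three domains.
#' @param verbal_fraction Probability a simulated subject is verbal
#'   (default 1, so every sheet shares the verbal communication cutoff).
#' @return A list of class `near_cutoff_config`.
#' @export
near_cutoff_config <- function(n = 1000L, cutoffs = adir_cutoffs(), delta = 3L,
                               items = adir_items(), map = domain_map(items),
                               background_probs = c(`0` = 0.55, `1` = 0.25,
                                                    `2` = 0.15, `3` = 0.05),
                               verbal_fraction = 1) {
  if (delta < 1) abort("delta must be >= 1.", class = "adirshort_config_error")
  m_by_domain <- vapply(map, length, integer(1))
  cuts <- c(social = cutoffs$social_cut,
            communication = max(cutoffs$comm_cut_verbal, cutoffs$comm_cut_nonverbal),
            rrb = cutoffs$rrb_cut)
  too_small <- cuts - 1L > 2L * m_by_domain[names(cuts)]
  if (any(too_small)) {
    abort(sprintf("Domain(s) %s have too few items to absorb targets up to cutoff - 1.",
                  paste(names(cuts)[too_small], collapse = ", ")),
          class = "adirshort_config_error")
  }
  structure(list(n = n, cutoffs = cutoffs, delta = as.integer(delta),
                 items = items, map = map, background_probs = background_probs,
                 verbal_fraction = verbal_fraction),
            class = "near_cutoff_config")
}

#' Simulate near-cutoff non-spectrum controls
#'
#' Generates sheets whose three recoded domain totals each fall close to
#' but strictly below the diagnostic cutoffs: for every sheet and domain a
#' target total is drawn uniformly from `[max(0, cutoff - delta),
#' cutoff - 1]` and allocated uniformly across that domain's items; items
#' outside the domains follow the configured background distribution. Every
#' output sheet therefore corresponds to an official non-spectrum
#' classification while representing behaviourally borderline subjects.
#'
#' @param cfg A [near_cutoff_config()].
#' @param seed Integer seed.
#' @return Answer-sheet tibble with `verbal` and
#'   `diagnosis = "non_spectrum"`.
#' @export
simulate_near_cutoff_controls <- function(cfg = near_cutoff_config(), seed = 1L) {
  n <- cfg$n
  abbr <- cfg$items$abbreviation
  withr::with_seed(seed, {
    verbal <- runif(n) < cfg$verbal_fraction
    comm_cut <- ifelse(verbal, cfg$cutoffs$comm_cut_verbal,
                       cfg$cutoffs$comm_cut_nonverbal)
    raw <- matrix(0L, n, length(abbr), dimnames = list(NULL, abbr))
    bg_items <- setdiff(abbr, unlist(cfg$map, use.names = FALSE))
    if (length(bg_items) > 0) {
      codes <- as.integer(names(cfg$background_probs))
      raw[, bg_items] <- sample(codes, n * length(bg_items), replace = TRUE,
                                prob = cfg$background_probs)
    }
    draw_domain <- function(cut_vec, item_set) {
      lo <- pmax(0L, cut_vec - cfg$delta)
      hi <- cut_vec - 1L
      targets <- lo + floor(runif(n) * (hi - lo + 1L))
      allocate_totals(targets, length(item_set))
    }
    raw[, cfg$map$social] <- draw_domain(rep(cfg$cutoffs$social_cut, n), cfg$map$social)
    raw[, cfg$map$communication] <- draw_domain(comm_cut, cfg$map$communication)
    raw[, cfg$map$rrb] <- draw_domain(rep(cfg$cutoffs$rrb_cut, n), cfg$map$rrb)
  })
  out <- dplyr::bind_cols(
    tibble(subject_id = sprintf("sim_near_%04d", seq_len(n)),
           verbal = verbal, diagnosis = "non_spectrum"),
    as_tibble(as.data.frame(raw))
  )
  out
}
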