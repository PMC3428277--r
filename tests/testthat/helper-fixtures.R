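# Shared fixtures, built in code at test time.

# Hand-built reference tree: root 0.5; splitter on q (< 1) whose low child
# (-2.0) carries a nested splitter on r (< 2) with children -0.5 / +0.1,
# and whose high child is +1.0.
manual_tree <- function() {
  m <- adirshort:::new_adtree(0.5, items = c("q", "r"), epsilon = 1)
  m <- adirshort:::adtree_add_split(m, pred_id = 1L, item = "q", threshold = 1,
                                    lo_value = -2.0, hi_value = 1.0)
  # nested under the low child (pred_id 2)
  adirshort:::adtree_add_split(m, pred_id = 2L, item = "r", threshold = 2,
                               lo_value = -0.5, hi_value = 0.1)
}

small_cohort <- function(seed = 11, n_cases = 120, n_controls = 30) {
  generate_cohort(cohort_config(n_cases = n_cases, n_controls = n_controls),
                  seed = seed)
}

random_sheets <- function(n, items, seed) {
  withr::with_seed(seed, {
    cols <- lapply(items, function(it) sample(0:2, n, replace = TRUE))
  })
  names(cols) <- items
  dplyr::bind_cols(tibble::tibble(subject_id = as.character(seq_len(n))),
                   tibble::as_tibble(cols))
}
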