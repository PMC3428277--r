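# ADI-R data model: item definitions, raw-code recoding, exception-code
# exclusion, domain scoring and the instrument's diagnostic algorithm.

#' The seven-item published subset
#'
#' Abbreviations of the seven ADI-R items (question numbers 29, 35, 48, 49,
#' 50, 64 and 86) that were found sufficient to separate autism from
#' non-spectrum in retrospective analyses of the full instrument. Shipped as
#' a named constant for questionnaire-shortening use.
#'
#' @format Character vector of length 7.
#' @export
published_subset <- c(
  "compsl5", "conver5", "play5", "peerpl5", "gaze5", "grplay5", "ageabn"
)

# Synthetic (non-canonical) item -> behavioural-domain assignment used by the
# default instrument and by the simulators. The true ADI-R algorithm item
# lists are licensed and not reproduced here.
.SOCIAL_ITEMS <- c(31L, 33L, 36L, 38L, 40L, 42L, 45L, 47L, 49L, 50L, 52L, 55L, 57L, 59L, 64L)
.COMM_ITEMS <- c(29L, 34L, 35L, 37L, 39L, 41L, 44L, 46L, 48L, 51L, 54L, 56L, 60L)
.RRB_ITEMS <- 67:74

#' Default ADI-R-style instrument definition
#'
#' Builds the 93-item instrument table used throughout the package: item
#' number, abbreviation (the seven published-subset items keep their
#' repository question codes; the rest are generic `qNN` codes), the
#' behavioural domain each item contributes to under the package's synthetic
#' domain mapping, and a short description. The domain assignment
#' (15 social, 13 communication, 8 restricted/repetitive items) is a
#' documented stand-in: the canonical ADI-R algorithm item lists are not
#' public, so the mapping is configurable wherever it is consumed.
#'
#' @return A tibble with columns `item_id`, `abbreviation`, `domain`
#'   (one of `"social"`, `"communication"`, `"rrb"`, `"none"`) and
#'   `description`.
#' @examples
#' items <- adir_items()
#' dplyr::count(items, domain)
#' @export
adir_items <- function() {
  named <- c(
    "29" = "compsl5", "35" = "conver5", "48" = "play5", "49" = "peerpl5",
    "50" = "gaze5", "64" = "grplay5", "86" = "ageabn"
  )
  descriptions <- c(
    "29" = "Comprehension of simple language (most abnormal 4-5)",
    "35" = "Reciprocal conversation (when verbal)",
    "48" = "Imaginative play (most abnormal 4-5)",
    "49" = "Imaginative play with peers (most abnormal 4-5)",
    "50" = "Direct gaze (most abnormal 4-5)",
    "64" = "Group play with peers (most abnormal 4-5)",
    "86" = "Age when abnormality first evident"
  )
  ids <- 1:93
  abbr <- sprintf("q%02d", ids)
  abbr[as.integer(names(named))] <- unname(named)
  domain <- rep("none", 93)
  domain[.SOCIAL_ITEMS] <- "social"
  domain[.COMM_ITEMS] <- "communication"
  domain[.RRB_ITEMS] <- "rrb"
  desc <- paste("ADI-R style item", ids)
  desc[as.integer(names(descriptions))] <- unname(descriptions)
  tibble(
    item_id = as.integer(ids),
    abbreviation = abbr,
    domain = domain,
    description = desc
  )
}

#' Item-to-domain mapping as a named list
#'
#' @param items Instrument table as returned by [adir_items()].
#' @return Named list with character vectors `social`, `communication`,
#'   `rrb` of item abbreviations.
#' @export
domain_map <- function(items = adir_items()) {
  split(items$abbreviation, items$domain)[c("social", "communication", "rrb")]
}

#' ADI-R diagnostic algorithm cutoffs
#'
#' Defaults are the instrument's published minimum domain totals:
#' 10 for social interaction, 8 (verbal) or 7 (nonverbal) for communication
#' and language, and 3 for restricted and stereotyped behaviours.
#'
#' @param social_cut,comm_cut_verbal,comm_cut_nonverbal,rrb_cut Positive
#'   integer cutoffs.
#' @return A named list of the four cutoffs.
#' @export
adir_cutoffs <- function(social_cut = 10L, comm_cut_verbal = 8L,
                         comm_cut_nonverbal = 7L, rrb_cut = 3L) {
  vals <- c(social_cut, comm_cut_verbal, comm_cut_nonverbal, rrb_cut)
  if (any(vals <= 0) || any(vals != as.integer(vals))) {
    abort("All cutoffs must be strictly positive integers.", class = "adirshort_config_error")
  }
  list(
    social_cut = as.integer(social_cut),
    comm_cut_verbal = as.integer(comm_cut_verbal),
    comm_cut_nonverbal = as.integer(comm_cut_nonverbal),
    rrb_cut = as.integer(rrb_cut)
  )
}

#' Recode a raw ADI-R answer for scoring
#'
#' Severity codes 0-2 map to themselves, the extreme-severity code 3 is
#' collapsed to 2, and the exception codes 7 ("abnormality not of the type
#' specified"), 8 ("not applicable") and 9 ("not known") are set to 0.
#'
#' @param raw Integer vector of raw codes in \{0,1,2,3,7,8,9\}.
#' @param item,subject Optional identifiers used to make validation errors
#'   traceable.
#' @return Integer vector of recoded scores in \{0,1,2\}.
#' @examples
#' recode_answer(c(0, 1, 2, 3, 7, 8, 9))
#' @export
recode_answer <- function(raw, item = NULL, subject = NULL) {
  raw <- as.integer(raw)
  bad <- which(!raw %in% ALLOWED_RAW_CODES | is.na(raw))
  if (length(bad) > 0) {
    where <- paste0(
      if (!is.null(item)) paste0(" item ", item[pmin(bad[1], length(item))]) else "",
      if (!is.null(subject)) paste0(" subject ", subject[pmin(bad[1], length(subject))]) else ""
    )
    abort(
      sprintf("Invalid raw answer code '%s'%s: allowed codes are 0,1,2,3,7,8,9.",
              raw[bad[1]], where),
      class = "adirshort_validation_error"
    )
  }
  out <- raw
  out[raw == 3L] <- 2L
  out[raw %in% EXCEPTION_CODES] <- 0L
  out
}

#' Recode a cohort of answer sheets into a scoring matrix
#'
#' Applies [recode_answer()] elementwise to the retained items and attaches
#' the class label used by the classifiers: autism = -1, non-spectrum = +1
#' (the sign convention under which a negative classifier score reads as
#' autism). Sheets with `diagnosis == "unknown"` are dropped with a warning,
#' never silently.
#'
#' @param sheets Answer-sheet tibble (one row per subject, raw item columns).
#' @param retained Character vector of item abbreviations to keep; defaults
#'   to every item column present.
#' @return Tibble with `subject_id`, `age_months`/`verbal` when present,
#'   `label`, and one recoded score column per retained item.
#' @examples
#' sheets <- tibble::tibble(
#'   subject_id = c("a", "b"), diagnosis = c("autism", "non_spectrum"),
#'   q1 = c(0L, 2L), q2 = c(3L, 1L), q3 = c(9L, 7L)
#' )
#' recode_cohort(sheets)
#' @export
recode_cohort <- function(sheets, retained = NULL) {
  if (is.null(retained)) retained <- item_cols(sheets)
  if (length(retained) == 0) {
    abort("No retained items: cannot build a recoded matrix.",
          class = "adirshort_validation_error")
  }
  missing_items <- setdiff(retained, names(sheets))
  if (length(missing_items) > 0) {
    abort(paste0("Answer sheets lack retained item(s): ",
                 paste(missing_items, collapse = ", ")),
          class = "adirshort_validation_error")
  }
  unknown <- !sheets$diagnosis %in% c("autism", "non_spectrum")
  if (any(unknown)) {
    warn(sprintf("Excluding %d sheet(s) with unknown diagnosis: %s",
                 sum(unknown),
                 paste(utils::head(sheets$subject_id[unknown], 5), collapse = ", ")))
    sheets <- sheets[!unknown, , drop = FALSE]
  }
  keep_meta <- intersect(c("subject_id", "age_months", "verbal"), names(sheets))
  out <- sheets[, keep_meta, drop = FALSE]
  out$label <- diagnosis_to_label(sheets$diagnosis)
  for (it in retained) {
    out[[it]] <- recode_answer(sheets[[it]], item = it, subject = sheets$subject_id)
  }
  as_tibble(out)
}

#' Identify items to exclude for exception-code prevalence
#'
#' An item is excluded when the fraction of its raw answers that are
#' exception codes (7, 8, 9) strictly exceeds `threshold` ("a majority" at
#' the default 0.5), plus any abbreviation force-listed in `special_items`
#' (e.g. special isolated skills or optional hand-written items).
#' Exclusion depends only on per-item answer marginals.
#'
#' @param sheets Answer-sheet tibble with raw codes.
#' @param threshold Fraction in (0, 1]; default 0.5 (strict majority).
#' @param special_items Character vector of abbreviations excluded
#'   regardless of their answers.
#' @return Character vector of excluded item abbreviations.
#' @export
identify_excluded_items <- function(sheets, threshold = 0.5,
                                    special_items = character()) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1].", class = "adirshort_config_error")
  }
  items <- item_cols(sheets)
  frac <- vapply(items, function(it) mean(sheets[[it]] %in% EXCEPTION_CODES),
                 numeric(1))
  excluded <- items[frac > threshold]
  union(excluded, intersect(special_items, items))
}

#' Domain totals for recoded sheets
#'
#' Sums recoded scores within the three ADI-R behavioural domains for each
#' subject. Totals are invariant to item order.
#'
#' @param recoded Recoded tibble (scores in 0-2), e.g. from
#'   [recode_cohort()].
#' @param map Item-to-domain mapping, a named list as from [domain_map()].
#' @return Tibble with `subject_id` (when present) and integer columns
#'   `social`, `communication`, `rrb`.
#' @export
domain_scores <- function(recoded, map = domain_map()) {
  needed <- unlist(map, use.names = FALSE)
  missing_items <- setdiff(needed, names(recoded))
  if (length(missing_items) > 0) {
    abort(paste0("Recoded data lack algorithm item(s): ",
                 paste(missing_items, collapse = ", ")),
          class = "adirshort_validation_error")
  }
  total_over <- function(cols) {
    m <- as.matrix(recoded[, cols, drop = FALSE])
    as.integer(rowSums(m))
  }
  out <- tibble(
    social = total_over(map$social),
    communication = total_over(map$communication),
    rrb = total_over(map$rrb)
  )
  if ("subject_id" %in% names(recoded)) {
    out <- tibble(subject_id = recoded$subject_id) %>% dplyr::bind_cols(out)
  }
  out
}

#' Classify sheets with the ADI-R domain-cutoff algorithm
#'
#' A subject meets the autism criterion when all three domain totals meet or
#' exceed their cutoffs: social >= 10, communication >= 8 (verbal) or
#' >= 7 (nonverbal), restricted/repetitive >= 3 by default. The
#' meets-or-exceeds reading is the standard convention for the instrument's
#' "minimum cutoffs".
#'
#' @param ds Domain-score tibble from [domain_scores()].
#' @param verbal Logical vector (recycled) giving each subject's verbal
#'   status, which selects the communication cutoff.
#' @param cutoffs Cutoff list from [adir_cutoffs()].
#' @return Character vector, `"autism"` or `"non_spectrum"`, one per row.
#' @examples
#' ds <- tibble::tibble(social = c(10, 9), communication = c(8, 20), rrb = c(3, 20))
#' adir_algorithm_classify(ds, verbal = TRUE)
#' @export
adir_algorithm_classify <- function(ds, verbal, cutoffs = adir_cutoffs()) {
  comm_cut <- ifelse(verbal, cutoffs$comm_cut_verbal, cutoffs$comm_cut_nonverbal)
  autism <- ds$social >= cutoffs$social_cut &
    ds$communication >= comm_cut &
    ds$rrb >= cutoffs$rrb_cut
  ifelse(autism, "autism", "non_spectrum")
}

#' Filter answer sheets by age
#'
#' Retains subjects with `min_years <= age < max_years` (half-open
#' interval). Ages are stored in months; year bounds convert at 12 months
#' per year. Either bound may be `NULL`: a max-only filter supports the
#' under-5 subgroup analysis.
#'
#' @param sheets Answer-sheet tibble with an `age_months` column.
#' @param min_years,max_years Age bounds in years, or `NULL` for unbounded.
#' @return The filtered tibble.
#' @examples
#' sheets <- tibble::tibble(subject_id = letters[1:4],
#'                          age_months = c(58L, 60L, 202L, 204L))
#' filter_by_age(sheets, 5, 17)$subject_id
#' @export
filter_by_age <- function(sheets, min_years = NULL, max_years = NULL) {
  keep <- rep(TRUE, nrow(sheets))
  if (!is.null(min_years)) keep <- keep & sheets$age_months >= min_years * 12
  if (!is.null(max_years)) keep <- keep & sheets$age_months < max_years * 12
  sheets[keep, , drop = FALSE]
}

#' Read and write answer-sheet files
#'
#' Answer sheets are stored as delimited text with a header row:
#' `subject_id`, `age_months`, `verbal`, `diagnosis`, then one column per
#' item named by abbreviation, codes written as bare integers (9 = not
#' known).
#'
#' @param path File path.
#' @param sheets Answer-sheet tibble.
#' @param delim Field delimiter, comma by default.
#' @return `read_answer_sheets()` returns the tibble;
#'   `write_answer_sheets()` returns `path` invisibly.
#' @export
read_answer_sheets <- function(path, delim = ",") {
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  out$subject_id <- as.character(out$subject_id)
  if ("age_months" %in% names(out)) out$age_months <- as.integer(out$age_months)
  if ("verbal" %in% names(out)) out$verbal <- as.logical(out$verbal)
  for (it in item_cols(out)) out[[it]] <- as.integer(out[[it]])
  out
}

#' @rdname read_answer_sheets
#' @export
write_answer_sheets <- function(sheets, path, delim = ",") {
  readr::write_delim(sheets, path, delim = delim)
  invisible(path)
}

#' Read and write instrument configuration
#'
#' The instrument definition (items plus domain mapping) is stored as a
#' versioned YAML document so that non-default mappings can be supplied as
#' data rather than code.
#'
#' @param items Instrument tibble as from [adir_items()].
#' @param path File path.
#' @return `read_instrument()` returns the instrument tibble;
#'   `write_instrument()` returns `path` invisibly.
#' @export
write_instrument <- function(items, path) {
  doc <- list(
    format_version = 1L,
    items = purrr::pmap(items, function(item_id, abbreviation, domain, description) {
      list(item_id = item_id, abbreviation = abbreviation,
           domain = domain, description = description)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$items)) {
    abort("Instrument file has no 'items' section.", class = "adirshort_config_error")
  }
  purrr::map_dfr(doc$items, function(it) {
    tibble(item_id = as.integer(it$item_id), abbreviation = it$abbreviation,
           domain = it$domain, description = it$description %||% "")
  })
}
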