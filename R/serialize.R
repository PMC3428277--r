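# Model files: human-readable JSON with explicit node nesting, shared by
# the ADTree and the baseline learners via a "model_type" tag. Numbers are
# written at full precision so a round-trip reproduces scores exactly.

MODEL_FORMAT_VERSION <- 1L

adtree_to_nested <- function(model) {
  build <- function(pred_id) {
    node <- list(value = model$pred_nodes$value[model$pred_nodes$pred_id == pred_id])
    kids <- model$splits[model$splits$parent_pred == pred_id, , drop = FALSE]
    node$splits <- purrr::pmap(kids, function(split_id, parent_pred, item,
                                              threshold, lo_pred, hi_pred) {
      list(split_id = split_id, item = item, threshold = threshold,
           lo = build(lo_pred), hi = build(hi_pred))
    })
    node
  }
  build(1L)
}

parse_nested_node <- function(node, path, state) {
  if (is.null(node$value) || !is.finite(as.numeric(node$value))) {
    abort(sprintf("Model parse error at %s: prediction value missing or not finite.", path),
          class = "adirshort_parse_error")
  }
  tmp_id <- state$next_tmp
  state$next_tmp <- state$next_tmp + 1L
  state$preds[[length(state$preds) + 1L]] <-
    list(tmp_id = tmp_id, value = as.numeric(node$value))
  for (sp in node$splits %||% list()) {
    spath <- paste0(path, "/split ", sp$split_id %||% "?")
    if (is.null(sp$item) || is.null(sp$threshold) ||
        !is.finite(as.numeric(sp$threshold))) {
      abort(sprintf("Model parse error at %s: splitter item/threshold missing.", spath),
            class = "adirshort_parse_error")
    }
    if (is.null(sp$lo) || is.null(sp$hi)) {
      abort(sprintf("Model parse error at %s: missing child node.", spath),
            class = "adirshort_parse_error")
    }
    lo_tmp <- parse_nested_node(sp$lo, paste0(spath, "/lo"), state)
    hi_tmp <- parse_nested_node(sp$hi, paste0(spath, "/hi"), state)
    state$splits[[length(state$splits) + 1L]] <- list(
      split_id = as.integer(sp$split_id %||% (length(state$splits) + 1L)),
      parent_tmp = tmp_id, item = sp$item,
      threshold = as.numeric(sp$threshold), lo_tmp = lo_tmp, hi_tmp = hi_tmp
    )
  }
  tmp_id
}

#' Write a fitted model to a structured text file
#'
#' Models are stored as JSON: a format version, a `model_type` tag
#' (`"adtree"`, `"stump"` or `"oner"`), and for ADTrees the recursively
#' nested prediction/splitter node structure at full numeric precision, so
#' that a read-back model scores any sheet identically.
#'
#' @param model A fitted `adtree`, `stump_model` or `oner_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- if (inherits(model, "adtree")) {
    list(
      format_version = MODEL_FORMAT_VERSION,
      model_type = "adtree",
      epsilon = model$epsilon,
      items = model$items,
      metadata = model$metadata,
      root = adtree_to_nested(model)
    )
  } else if (inherits(model, "stump_model")) {
    list(
      format_version = MODEL_FORMAT_VERSION, model_type = "stump",
      item = model$item, threshold = model$threshold,
      label_lo = model$label_lo, label_hi = model$label_hi
    )
  } else if (inherits(model, "oner_model")) {
    list(
      format_version = MODEL_FORMAT_VERSION, model_type = "oner",
      item = model$item,
      mapping = list(value = as.numeric(names(model$mapping)),
                     label = as.integer(unname(model$mapping))),
      default_label = model$default_label
    )
  } else {
    abort("Unsupported model class.", class = "adirshort_config_error")
  }
  # digits = I(17): significant-digit mode with enough digits to make the
  # double -> text -> double round-trip exact.
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a model file
#'
#' @param path Path to a file written by [write_model()].
#' @return The model object (`adtree`, `stump_model` or `oner_model`).
#' @export
read_model <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("Model parse error: ", conditionMessage(e)),
                              class = "adirshort_parse_error")
  )
  type <- doc$model_type %||% abort("Model file lacks model_type.",
                                    class = "adirshort_parse_error")
  switch(
    type,
    adtree = {
      state <- new.env()
      state$preds <- list()
      state$splits <- list()
      state$next_tmp <- 1L
      if (is.null(doc$root)) {
        abort("Model parse error at root: no root node.", class = "adirshort_parse_error")
      }
      parse_nested_node(doc$root, "root", state)
      preds <- bind_rows(lapply(state$preds, as_tibble))
      splits <- if (length(state$splits)) bind_rows(lapply(state$splits, as_tibble)) else NULL
      model <- new_adtree(preds$value[preds$tmp_id == 1L],
                          items = unlist(doc$items),
                          epsilon = doc$epsilon %||% 1,
                          metadata = doc$metadata %||% list())
      if (!is.null(splits)) {
        splits <- splits[order(splits$split_id), , drop = FALSE]
        # Reassign prediction ids in creation order: root, then each
        # split's lo/hi children in split_id order.
        id_map <- list(`1` = 1L)
        for (i in seq_len(nrow(splits))) {
          sp <- splits[i, ]
          parent_new <- id_map[[as.character(sp$parent_tmp)]]
          if (is.null(parent_new)) {
            abort(sprintf("Model parse error: split %d references an unknown parent.",
                          sp$split_id), class = "adirshort_parse_error")
          }
          val_of <- function(tmp) preds$value[preds$tmp_id == tmp]
          model <- adtree_add_split(model, pred_id = parent_new, item = sp$item,
                                    threshold = sp$threshold,
                                    lo_value = val_of(sp$lo_tmp),
                                    hi_value = val_of(sp$hi_tmp))
          np <- nrow(model$pred_nodes)
          id_map[[as.character(sp$lo_tmp)]] <- np - 1L
          id_map[[as.character(sp$hi_tmp)]] <- np
        }
      }
      model$iterations_used <- nrow(model$splits)
      model
    },
    stump = structure(
      list(item = doc$item, threshold = as.numeric(doc$threshold),
           label_lo = as.integer(doc$label_lo), label_hi = as.integer(doc$label_hi)),
      class = "stump_model"
    ),
    oner = {
      mp <- as.integer(unlist(doc$mapping$label))
      names(mp) <- as.character(as.numeric(unlist(doc$mapping$value)))
      structure(
        list(item = doc$item, mapping = mp,
             default_label = as.integer(doc$default_label)),
        class = "oner_model"
      )
    },
    abort(sprintf("Unknown model_type '%s'.", type), class = "adirshort_parse_error")
  )
}
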