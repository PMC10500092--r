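# Model persistence: schema-versioned JSON. Numbers are written at full
# precision (digits = NA) so a deserialised model predicts bit-identically.

MT_SCHEMA <- "mttree/1"

#' Serialize a tree model to JSON text
#'
#' @param model An `mttree`.
#' @return A single JSON string (schema-versioned).
#' @export
mt_serialize <- function(model) {
  stopifnot(inherits(model, "mttree"))
  doc <- list(
    schema = MT_SCHEMA,
    control = unclass(model$control),
    targets = lapply(model$targets, unclass),
    feature_info = list(
      names = as.list(model$feature_info$names),
      types = as.list(model$feature_info$types),
      levels = lapply(model$feature_info$levels, as.list)),
    surv_scales = lapply(model$surv_scales, function(m)
      list(times = m$times, haz = m$haz)),
    train_n = model$train_n,
    nodes = lapply(model$nodes, function(nd) {
      nd$summary <- lapply(nd$summary, function(s) {
        if (!is.null(s$prop)) s$prop <- as.list(s$prop)
        s
      })
      nd
    })
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly.
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                                null = "null", na = "null"))
}

#' Save / load a tree model
#'
#' @param model An `mttree`.
#' @param path File path.
#' @rdname mt_save
#' @export
mt_save <- function(model, path) {
  writeLines(mt_serialize(model), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname mt_save
#' @export
mt_load <- function(path) {
  if (!file.exists(path)) mt_stop_config(sprintf("file not found: %s", path))
  mt_deserialize(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Deserialize a tree model from JSON text
#'
#' @param text JSON produced by [mt_serialize()] (any schema-compatible
#'   hand-written document also loads).
#' @return An `mttree` whose predictions are identical to the serialised
#'   model's.
#' @export
mt_deserialize <- function(text) {
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e)
      mt_stop_parse(sprintf("malformed model document: %s", conditionMessage(e))))
  if (!identical(doc$schema, MT_SCHEMA))
    mt_stop_config(sprintf(
      "unsupported model schema '%s' (expected '%s')",
      doc$schema %||% "<missing>", MT_SCHEMA))
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  targets <- mt_targets(lapply(doc$targets, function(t)
    mt_target(t$name, t$type, t$weight, event = t$event,
              exposure = t$exposure)))
  control <- do.call(mt_control, doc$control)
  fi <- doc$feature_info
  feature_info <- list(
    names = as.character(unlist(fi$names)),
    types = stats::setNames(as.character(unlist(fi$types)),
                            as.character(unlist(fi$names))),
    levels = lapply(fi$levels, function(l) as.character(unlist(l))))
  surv_scales <- lapply(doc$surv_scales, function(m)
    structure(list(times = num(m$times) %||% numeric(0),
                   haz = num(m$haz) %||% numeric(0)),
              class = "mt_surv_scale"))
  nodes <- lapply(doc$nodes, function(nd) {
    out <- list(
      id = as.integer(nd$id), depth = as.integer(nd$depth),
      n = as.integer(nd$n), is_leaf = isTRUE(nd$is_leaf),
      split = if (!is.null(nd$split)) list(
        feature = nd$split$feature, kind = nd$split$kind,
        threshold = if (is.null(nd$split$threshold)) NA_real_
                    else as.numeric(nd$split$threshold),
        level = if (is.null(nd$split$level)) NA_character_
                else as.character(nd$split$level),
        missing_side = nd$split$missing_side),
      children = if (!is.null(nd$children))
        as.integer(unlist(nd$children)),
      loss = lapply(nd$loss, function(l)
        list(value = as.numeric(l$value), n = as.integer(l$n))),
      summary = lapply(seq_along(targets), function(j) {
        s <- nd$summary[[j]]
        switch(targets[[j]]$type,
          continuous = list(mean = as.numeric(s$mean), n = as.integer(s$n)),
          categorical = list(
            modal = as.character(s$modal),
            prop = stats::setNames(as.numeric(unlist(s$prop)),
                                   names(s$prop))),
          count = list(rate = as.numeric(s$rate),
                       exposure = as.numeric(s$exposure)),
          survival = list(rate = as.numeric(s$rate),
                          events = as.numeric(s$events)))
      }),
      score = if (!is.null(nd$score)) lapply(nd$score, function(v)
        if (is.list(v)) as.numeric(unlist(v)) else v))
    out
  })
  required <- c("id", "depth", "n")
  for (nd in nodes) if (any(vapply(nodes[[1]][required], is.null, TRUE)))
    mt_stop_parse("model document is missing node fields")
  structure(list(schema = MT_SCHEMA, nodes = nodes, targets = targets,
                 control = control, feature_info = feature_info,
                 surv_scales = surv_scales,
                 train_n = as.integer(doc$train_n %||% NA_integer_),
                 train_leaf = NULL),
            class = "mttree")
}
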