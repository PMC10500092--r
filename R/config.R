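#' Read a model configuration document
#'
#' The configuration is JSON with two sections: `targets`, an array of
#' objects with keys `name`, `type`, `weight` (default 1), `event`
#' (survival only) and `exposure` (count only); and `params`, an object of
#' [mt_control] fields. Absent params take the documented defaults.
#'
#' @param path File path of the JSON document.
#' @return List with elements `targets` ([mt_targets]) and `control`
#'   ([mt_control]).
#' @export
mt_read_config <- function(path) {
  if (!file.exists(path)) mt_stop_config(sprintf("file not found: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      mt_stop_parse(sprintf("cannot parse config '%s': %s", path,
                            conditionMessage(e))))
  if (is.null(doc$targets))
    mt_stop_config(sprintf("config '%s' lacks a 'targets' section", path))
  targets <- mt_targets(lapply(doc$targets, function(t) {
    if (is.null(t$name) || is.null(t$type))
      mt_stop_config("every target needs 'name' and 'type'")
    mt_target(t$name, t$type, weight = t$weight %||% 1,
              event = t$event, exposure = t$exposure)
  }))
  params <- doc$params %||% list()
  bad <- setdiff(names(params), names(formals(mt_control)))
  if (length(bad))
    mt_stop_config(sprintf("unknown params key(s): %s",
                           paste(bad, collapse = ", ")))
  control <- do.call(mt_control, params)
  list(targets = targets, control = control)
}

# Tuning-grid document: {"k": 5, "seed": 7, "grid": {"d": [1,2], ...}}
mt_read_grid <- function(path) {
  if (!file.exists(path)) mt_stop_config(sprintf("file not found: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e)
      mt_stop_parse(sprintf("cannot parse grid '%s': %s", path,
                            conditionMessage(e))))
  if (is.null(doc$grid) || !length(doc$grid))
    mt_stop_config(sprintf("grid file '%s' lacks a non-empty 'grid' object",
                           path))
  list(grid = as.list(doc$grid),
       k = as.integer(doc$k %||% 5L),
       seed = if (!is.null(doc$seed)) as.integer(doc$seed) else NULL)
}

# Plant-spec document for `simulate`: any mt_plant_spec argument.
mt_read_plant_spec <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e)
      mt_stop_parse(sprintf("cannot parse spec '%s': %s", path,
                            conditionMessage(e))))
  bad <- setdiff(names(doc), names(formals(mt_plant_spec)))
  if (length(bad))
    mt_stop_config(sprintf("unknown spec key(s): %s",
                           paste(bad, collapse = ", ")))
  if (!is.null(doc$planted)) doc$planted <- unlist(doc$planted)
  if (!is.null(doc$cat_probs)) doc$cat_probs <- as.matrix(doc$cat_probs)
  do.call(mt_plant_spec, doc)
}
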