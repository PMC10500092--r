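MT_TARGET_TYPES <- c("continuous", "categorical", "count", "survival")

#' Declare one model endpoint
#'
#' A target specification names an outcome column, its type, its weight in
#' cross-target aggregation, and any auxiliary columns: survival targets
#' require a 0/1 event-indicator column, count targets may carry a positive
#' exposure column (person-time, library size, ...).
#'
#' @param name Column name of the outcome.
#' @param type One of `"continuous"`, `"categorical"`, `"count"`,
#'   `"survival"`.
#' @param weight Non-negative weight; targets with weight 0 are carried along
#'   but excluded from every aggregation and selection rule.
#' @param event Event-indicator column name; required iff `type = "survival"`.
#' @param exposure Optional exposure column name; allowed iff `type = "count"`.
#' @return An object of class `mt_target`.
#' @examples
#' mt_target("os_months", "survival", event = "os_event")
#' @export
mt_target <- function(name, type, weight = 1, event = NULL, exposure = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    mt_stop_config("target 'name' must be a non-empty string")
  if (!is.character(type) || length(type) != 1L || !(type %in% MT_TARGET_TYPES))
    mt_stop_config(sprintf("target '%s': type must be one of %s", name,
                           paste(MT_TARGET_TYPES, collapse = ", ")))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    mt_stop_config(sprintf("target '%s': weight must be a non-negative real",
                           name))
  if (type == "survival") {
    if (is.null(event) || !is.character(event) || length(event) != 1L)
      mt_stop_config(sprintf(
        "survival target '%s' requires an 'event' indicator column", name))
  } else if (!is.null(event)) {
    mt_stop_config(sprintf(
      "target '%s': 'event' is only allowed for survival targets", name))
  }
  if (!is.null(exposure) && type != "count")
    mt_stop_config(sprintf(
      "target '%s': 'exposure' is only allowed for count targets", name))
  structure(list(name = name, type = type, weight = as.numeric(weight),
                 event = event, exposure = exposure),
            class = "mt_target")
}

#' Bundle target specifications
#'
#' @param ... `mt_target` objects (or a single list of them).
#' @return An object of class `mt_targets` (a list of `mt_target`).
#' @export
mt_targets <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && !inherits(ts[[1]], "mt_target") && is.list(ts[[1]]))
    ts <- ts[[1]]
  if (!length(ts)) mt_stop_config("at least one target must be declared")
  for (t in ts) if (!inherits(t, "mt_target"))
    mt_stop_config("all arguments must be mt_target objects")
  nms <- vapply(ts, `[[`, "", "name")
  if (anyDuplicated(nms))
    mt_stop_config("duplicate target names are not allowed")
  structure(ts, names = nms, class = "mt_targets")
}

#' @export
print.mt_targets <- function(x, ...) {
  cat(sprintf("%d target(s):\n", length(x)))
  for (t in x) {
    aux <- if (!is.null(t$event)) sprintf(" event=%s", t$event)
           else if (!is.null(t$exposure)) sprintf(" exposure=%s", t$exposure)
           else ""
    cat(sprintf("  %s (%s, wt=%g%s)\n", t$name, t$type, t$weight, aux))
  }
  invisible(x)
}

# Columns a target set consumes (outcomes + auxiliaries).
mt_target_columns <- function(targets) {
  unique(unlist(lapply(targets, function(t)
    c(t$name, t$event, t$exposure))))
}

mt_check_weighted <- function(targets) {
  w <- vapply(targets, `[[`, 0, "weight")
  if (!any(w > 0))
    mt_stop_config("at least one target must have weight > 0")
  invisible(TRUE)
}
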