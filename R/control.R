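#' Split-evaluation methods
#'
#' The seven rules available for combining per-target gains and p-values
#' into a single split ranking.
#'
#' @format Character vector of method names.
#' @export
MT_EVAL_METHODS <- c("avgIG", "maxIG", "mostIG",
                     "avgPVal", "minPVal", "mostPVal", "splitError")

#' Tree induction hyperparameters
#'
#' Collects every tuning knob of the engine, with rpart-like defaults.
#'
#' @param evalmethod One of [MT_EVAL_METHODS]: `"avgIG"` (weight-normalised
#'   mean proportion information gain), `"maxIG"` (best single-target
#'   proportion IG), `"mostIG"` (meaningful IG, i.e. proportion IG >=
#'   `IGcutoff`, in the most targets), `"avgPVal"` (lowest mean p-value over
#'   significant targets), `"minPVal"` (lowest p-value down-weighted by the
#'   number of significant targets), `"mostPVal"` (significant IG in the most
#'   targets), or `"splitError"` (subtree lookahead on multi-target error).
#' @param d Maximum tree depth (root has depth 0). `d = 0` yields a
#'   single-leaf model.
#' @param nodesize Minimum number of rows a node must hold to be considered
#'   for splitting.
#' @param splitmin Minimum number of rows each child of a split must retain.
#' @param cp Complexity parameter: a split is accepted only when its
#'   weight-normalised mean proportion IG is at least `cp` (pre-pruning gate).
#' @param reuse May a feature appear more than once on a root-to-leaf path?
#' @param alpha Significance level used when counting targets with a
#'   significant gain (p-value based methods).
#' @param IGcutoff Proportion-IG threshold above which a target's gain is
#'   counted as "meaningful" (`mostIG`).
#' @param parallelsplit Number of top-ranked candidates expanded during
#'   `splitError` lookahead.
#' @param paralleldepth Depth of the subtree grown beneath each lookahead
#'   candidate (1 = the candidate split itself).
#' @param seed Integer seed used by stochastic helpers (fold assignment).
#' @return An object of class `mt_control`.
#' @examples
#' mt_control(evalmethod = "maxIG", d = 2)
#' @export
mt_control <- function(evalmethod = "avgIG", d = 4L, nodesize = 20L,
                       splitmin = 7L, cp = 0.01, reuse = TRUE, alpha = 0.05,
                       IGcutoff = 0.10, parallelsplit = 5L, paralleldepth = 2L,
                       seed = 42L) {
  if (!is.character(evalmethod) || length(evalmethod) != 1L ||
      !(evalmethod %in% MT_EVAL_METHODS)) {
    mt_stop_config(sprintf(
      "unknown evalmethod '%s'; valid options are: %s",
      paste(evalmethod, collapse = ","), paste(MT_EVAL_METHODS, collapse = ", ")))
  }
  chk_int <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
      mt_stop_config(sprintf("'%s' must be an integer >= %d (got %s)",
                             nm, min, paste(x, collapse = ",")))
    as.integer(x)
  }
  chk_real <- function(x, nm, lo, hi, lo_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) && x <= hi
    if (!ok) mt_stop_config(sprintf("'%s' out of range (got %s)", nm,
                                    paste(x, collapse = ",")))
    as.numeric(x)
  }
  if (!is.logical(reuse) || length(reuse) != 1L || is.na(reuse))
    mt_stop_config("'reuse' must be TRUE or FALSE")
  structure(list(
    evalmethod = evalmethod,
    d = chk_int(d, "d", 0L),
    nodesize = chk_int(nodesize, "nodesize", 1L),
    splitmin = chk_int(splitmin, "splitmin", 1L),
    cp = chk_real(cp, "cp", 0, Inf),
    reuse = reuse,
    alpha = chk_real(alpha, "alpha", 0, 1, lo_open = TRUE),
    IGcutoff = chk_real(IGcutoff, "IGcutoff", 0, 1),
    parallelsplit = chk_int(parallelsplit, "parallelsplit", 1L),
    paralleldepth = chk_int(paralleldepth, "paralleldepth", 1L),
    seed = chk_int(seed, "seed", -.Machine$integer.max)
  ), class = "mt_control")
}

#' @export
print.mt_control <- function(x, ...) {
  cat("Multi-target tree control:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Merge a named list of overrides (e.g. a tuning-grid row) into a control.
mt_control_update <- function(control, overrides) {
  if (!length(overrides)) return(control)
  bad <- setdiff(names(overrides), names(control))
  if (length(bad))
    mt_stop_config(sprintf("unknown hyperparameter(s): %s",
                           paste(bad, collapse = ", ")))
  args <- utils::modifyList(unclass(control), overrides)
  do.call(mt_control, args)
}
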