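#' k-fold cross-validation fold assignment
#'
#' Partitions rows into `k` folds whose sizes differ by at most one,
#' stratified on the first weighted categorical target when one exists
#' (class counts per fold then also differ by at most one), otherwise
#' uniformly at random. Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param data An [mt_dataset].
#' @param k Number of folds, `2 <= k <= n_rows`.
#' @param targets Defaults to `data$targets`.
#' @param seed Integer seed.
#' @return List of `k` disjoint integer row-index vectors covering the data.
#' @export
mt_make_folds <- function(data, k, targets = data$targets, seed = 42L) {
  stopifnot(inherits(data, "mt_dataset"))
  n <- data$n_rows
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2L)
    mt_stop_config("'k' must be an integer >= 2")
  if (k > n)
    mt_stop_config(sprintf("k = %d exceeds the number of rows (%d)", k, n))
  strat <- NULL
  for (t in targets)
    if (t$weight > 0 && t$type == "categorical") { strat <- t; break }
  with_mt_seed(seed, {
    ord <- if (is.null(strat)) {
      sample.int(n)
    } else {
      y <- data$data[[strat$name]]
      unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        if (length(idx) > 1L) sample(idx) else idx
      }), use.names = FALSE)
    }
    fold <- rep_len(seq_len(k), n)
    lapply(seq_len(k), function(i) sort(ord[fold == i]))
  })
}

#' Grid-search hyperparameter tuning with k-fold cross-validation
#'
#' For every combination in the Cartesian product of `grid` and every fold:
#' grow a tree on the other folds and score the held-out fold with
#' [mt_evaluate()]; the combination minimising mean overall error wins,
#' ties broken toward simpler models (smaller `d`, then larger `cp`, then
#' first in grid order). One fold assignment is drawn per call so all
#' combinations are compared on the same folds.
#'
#' @param data An [mt_dataset].
#' @param targets Defaults to `data$targets`.
#' @param grid Named list of candidate value vectors; names must be
#'   [mt_control] fields (e.g. `list(d = 1:4, cp = c(0.01, 0.05))`).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment; defaults to `control$seed`.
#' @param control Base control supplying every field the grid leaves free.
#' @return An `mt_tune` object: `table` (one row per combination with
#'   per-fold overall errors, their mean and sd), `best` (the winning
#'   combination as a named list), `best_index`, and `folds`.
#' @export
mt_tune <- function(data, targets = data$targets, grid, k = 5L,
                    seed = NULL, control = mt_control()) {
  stopifnot(inherits(data, "mt_dataset"))
  if (!inherits(targets, "mt_targets")) targets <- mt_targets(targets)
  if (!is.list(grid) || is.null(names(grid)) || !all(nzchar(names(grid))))
    mt_stop_config("'grid' must be a named list of candidate values")
  bad <- setdiff(names(grid), names(control))
  if (length(bad))
    mt_stop_config(sprintf("unknown hyperparameter(s) in grid: %s",
                           paste(bad, collapse = ", ")))
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (!nrow(combos)) mt_stop_config("empty tuning grid")
  seed <- seed %||% control$seed
  folds <- mt_make_folds(data, k, targets, seed)

  errs <- matrix(NA_real_, nrow(combos), k)
  for (ci in seq_len(nrow(combos))) {
    hp <- mt_control_update(control, as.list(combos[ci, , drop = FALSE]))
    for (fi in seq_len(k)) {
      test_rows <- folds[[fi]]
      train <- mt_subset(data, setdiff(seq_len(data$n_rows), test_rows))
      test <- mt_subset(data, test_rows)
      fit <- mt_grow(train, targets, hp)
      errs[ci, fi] <- mt_evaluate(fit, test)$overall
    }
  }
  mean_err <- rowMeans(errs)
  sd_err <- apply(errs, 1, stats::sd)
  eff <- function(nm) {
    if (nm %in% names(combos)) combos[[nm]] else rep(control[[nm]],
                                                     nrow(combos))
  }
  best_index <- order(mean_err, eff("d"), -eff("cp"),
                      seq_len(nrow(combos)))[1]
  table <- cbind(combos,
                 as.data.frame(errs,
                               col.names = paste0("fold", seq_len(k))),
                 mean_error = mean_err, sd_error = sd_err)
  names(table)[seq_len(k) + ncol(combos)] <- paste0("fold", seq_len(k))
  structure(list(table = table, best = as.list(combos[best_index, ,
                                                      drop = FALSE]),
                 best_index = best_index, folds = folds, k = k,
                 seed = seed),
            class = "mt_tune")
}

#' @export
print.mt_tune <- function(x, ...) {
  cat(sprintf("Grid-search CV over %d combination(s), k = %d:\n",
              nrow(x$table), x$k))
  print(x$table, row.names = FALSE)
  cat("Best:", paste(names(x$best), unlist(x$best), sep = "=",
                     collapse = ", "), "\n")
  invisible(x)
}
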