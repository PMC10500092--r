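# Candidate split enumeration and multi-target scoring.
#
# Two routes compute the same selection:
#  * the operation surface (enumerate_candidates / score_candidate /
#    select_split) materialises every candidate and scores it one at a time
#    -- transparent, used directly in tests and on small nodes;
#  * .mt_best_split scores all thresholds of a feature at once from prefix
#    sums -- used by mt_grow so induction stays fast on cohort-sized data.
# A property test asserts the two routes pick identical splits.

# Bound on candidate thresholds per numeric feature per node. Large enough
# that cohort-scale nodes are enumerated exhaustively (so planted cutpoints
# stay reachable); features with more distinct values fall back to
# quantile-spaced gap midpoints.
MAX_NUMERIC_CUTS <- 2048L

new_split_candidate <- function(feature, kind, threshold = NA_real_,
                                level = NA_character_, left_rows, right_rows,
                                missing_side = "left", n_missing = 0L) {
  structure(list(feature = feature, kind = kind, threshold = threshold,
                 level = level, left_rows = left_rows,
                 right_rows = right_rows, missing_side = missing_side,
                 n_missing = n_missing),
            class = "mt_split_candidate")
}

# Candidate cut positions for a numeric feature: midpoints between
# consecutive distinct sorted values, thinned to MAX_NUMERIC_CUTS
# quantile-spaced gaps when there are more.
.numeric_cuts <- function(sv) {
  gaps <- which(diff(sv) > 0)
  if (!length(gaps)) return(list(idx = integer(0), thr = numeric(0)))
  thr <- (sv[gaps] + sv[gaps + 1L]) / 2
  if (length(gaps) > MAX_NUMERIC_CUTS) {
    sel <- unique(round(seq(1L, length(gaps), length.out = MAX_NUMERIC_CUTS)))
    gaps <- gaps[sel]; thr <- thr[sel]
  }
  list(idx = gaps, thr = thr)
}

#' Enumerate binarized candidate splits at a node
#'
#' Numeric features yield one candidate per midpoint between consecutive
#' distinct sorted values (thinned to 2048 quantile-spaced cuts when a
#' feature has more distinct values at the node); categorical features yield one
#' level-vs-rest candidate per level present. Rows with a missing feature
#' value are assigned to the larger side (ties to the left) and count toward
#' the `splitmin` checks; candidates leaving either side below
#' `hp$splitmin` are removed. Order is deterministic: feature column order,
#' then ascending threshold / first-appearance level order.
#'
#' @param data An `mt_dataset` restricted to the node's rows.
#' @param hp An [mt_control] object.
#' @param used_features Features already used on the path to this node
#'   (skipped when `hp$reuse` is `FALSE`).
#' @return List of `mt_split_candidate` (possibly empty). Row sets are
#'   indices into `data`'s rows.
#' @export
enumerate_candidates <- function(data, hp = mt_control(),
                                 used_features = character()) {
  stopifnot(inherits(data, "mt_dataset"))
  out <- list()
  n <- data$n_rows
  for (f in names(data$features)) {
    if (!hp$reuse && f %in% used_features) next
    x <- data$data[[f]]
    mis <- which(is.na(x))
    nm <- setdiff(seq_len(n), mis)
    if (data$features[[f]] == "numeric") {
      xs <- x[nm]
      o <- order(xs)
      cuts <- .numeric_cuts(xs[o])
      for (i in seq_along(cuts$thr)) {
        thr <- cuts$thr[i]
        lrel <- nm[x[nm] <= thr]
        rrel <- setdiff(nm, lrel)
        side <- if (length(lrel) >= length(rrel)) "left" else "right"
        if (side == "left") lrel <- c(lrel, mis) else rrel <- c(rrel, mis)
        if (length(lrel) < hp$splitmin || length(rrel) < hp$splitmin) next
        out[[length(out) + 1L]] <- new_split_candidate(
          f, "numeric_threshold", threshold = thr,
          left_rows = sort(lrel), right_rows = sort(rrel),
          missing_side = side, n_missing = length(mis))
      }
    } else {
      lvls <- data$feature_levels[[f]]
      lvls <- lvls[lvls %in% x[nm]]
      if (length(lvls) < 2L) next
      for (lv in lvls) {
        lrel <- nm[x[nm] == lv]
        rrel <- setdiff(nm, lrel)
        side <- if (length(lrel) >= length(rrel)) "left" else "right"
        if (side == "left") lrel <- c(lrel, mis) else rrel <- c(rrel, mis)
        if (length(lrel) < hp$splitmin || length(rrel) < hp$splitmin) next
        out[[length(out) + 1L]] <- new_split_candidate(
          f, "level_vs_rest", level = lv,
          left_rows = sort(lrel), right_rows = sort(rrel),
          missing_side = side, n_missing = length(mis))
      }
    }
  }
  out
}

# Per-target value/auxiliary vectors for scoring (survival times are used
# as stored -- mt_grow rescales them once at the root).
.mt_target_values <- function(data) {
  lapply(data$targets, function(t) {
    y <- data$data[[t$name]]
    aux <- switch(t$type,
      count = if (!is.null(t$exposure)) data$data[[t$exposure]]
              else rep(1, data$n_rows),
      survival = data$data[[t$event]],
      NULL)
    list(name = t$name, type = t$type, w = t$weight, y = y, aux = aux)
  })
}

.mt_node_losses <- function(tv, rows = NULL) {
  lapply(tv, function(z) {
    if (is.null(rows)) node_loss_for(z, z$y, z$aux)
    else node_loss_for(z, z$y[rows],
                       if (is.null(z$aux)) NULL else z$aux[rows])
  })
}

#' Per-target node losses of an `mt_dataset`
#'
#' @param data An `mt_dataset` (typically restricted to one node's rows).
#' @return List of `mt_node_loss` aligned to the target order.
#' @export
mt_node_losses <- function(data) {
  .mt_node_losses(.mt_target_values(data))
}

# Aggregate a vector of per-target (prop_ig, p) into the evalmethod score
# and selection keys. All vectors are over eligible targets only.
.mt_aggregate <- function(method, w, prop, p, alpha, IGcutoff) {
  if (!length(w)) {
    return(list(aggregate = NA_real_, key1 = -Inf, key2 = -Inf,
                wmean = 0, n_sig = 0L, n_meaningful = 0L))
  }
  wmean <- sum(w * prop) / sum(w)
  n_sig <- sum(p <= alpha)
  n_mean <- sum(prop >= IGcutoff)
  switch(method,
    avgIG = list(aggregate = wmean, key1 = wmean, key2 = 0),
    maxIG = list(aggregate = max(prop), key1 = max(prop), key2 = 0),
    mostIG = list(aggregate = n_mean, key1 = n_mean, key2 = wmean),
    avgPVal = {
      v <- if (n_sig > 0) mean(p[p <= alpha]) else Inf
      list(aggregate = v, key1 = -v, key2 = 0)
    },
    minPVal = {
      v <- min(p) / max(1L, n_sig)
      list(aggregate = v, key1 = -v, key2 = 0)
    },
    mostPVal = list(aggregate = n_sig, key1 = n_sig,
                    key2 = if (n_sig > 0) -mean(p[p <= alpha]) else -Inf),
    splitError = list(aggregate = wmean, key1 = wmean, key2 = 0)
  ) -> agg
  c(agg, list(wmean = wmean, n_sig = as.integer(n_sig),
              n_meaningful = as.integer(n_mean)))
}

#' Score one candidate split against all targets
#'
#' Computes each target's gain via [target_gain()] and the
#' evalmethod-specific aggregate. Targets with weight 0, and targets whose
#' parent loss is 0 (nothing left to explain), are excluded from every
#' aggregate.
#'
#' @param cand An `mt_split_candidate` from [enumerate_candidates()].
#' @param data The node-restricted `mt_dataset` the candidate refers to.
#' @param hp An [mt_control].
#' @param node_losses Optional precomputed [mt_node_losses()] of `data`.
#' @return An `mt_split_score`: `per_target` gains (target order),
#'   `aggregate`, `n_significant`, `n_meaningful`, `wmean_prop_ig`.
#' @export
score_candidate <- function(cand, data, hp = mt_control(),
                            node_losses = NULL) {
  tv <- .mt_target_values(data)
  if (is.null(node_losses)) node_losses <- .mt_node_losses(tv)
  gains <- vector("list", length(tv))
  for (j in seq_along(tv)) {
    z <- tv[[j]]
    ll <- node_loss_for(z, z$y[cand$left_rows],
                        if (is.null(z$aux)) NULL else z$aux[cand$left_rows])
    rl <- node_loss_for(z, z$y[cand$right_rows],
                        if (is.null(z$aux)) NULL else z$aux[cand$right_rows])
    gains[[j]] <- target_gain(node_losses[[j]], ll, rl, z$type)
  }
  w <- vapply(tv, `[[`, 0, "w")
  pv <- vapply(node_losses, `[[`, 0, "value")
  elig <- w > 0 & pv > 0
  prop <- vapply(gains, `[[`, 0, "prop_ig")
  p <- vapply(gains, `[[`, 0, "p_value")
  agg <- .mt_aggregate(hp$evalmethod, w[elig], prop[elig], p[elig],
                       hp$alpha, hp$IGcutoff)
  structure(list(per_target = gains, aggregate = agg$aggregate,
                 n_significant = agg$n_sig, n_meaningful = agg$n_meaningful,
                 wmean_prop_ig = agg$wmean, key1 = agg$key1, key2 = agg$key2),
            class = "mt_split_score")
}

#' Multi-target lookahead error of a subtree
#'
#' Weight-normalised mean, over weighted targets, of the fraction of the
#' subtree root's loss remaining in its leaves:
#' `sum_t w_t (sum_leaves loss_t / root_loss_t) / sum_t w_t`, a target with
#' zero root loss contributing 0. Lies in `[0, 1]` for convex losses.
#'
#' @param subtree_leaves List over leaves of per-target `mt_node_loss` lists.
#' @param root_losses Per-target `mt_node_loss` of the subtree root.
#' @param targets The [mt_targets] specification (for weights).
#' @return A single number.
#' @export
lookahead_error <- function(subtree_leaves, root_losses, targets) {
  w <- vapply(targets, `[[`, 0, "weight")
  keep <- w > 0
  if (!any(keep)) return(0)
  num <- 0
  for (j in which(keep)) {
    root <- root_losses[[j]]$value
    if (root <= 0) next
    leafsum <- sum(vapply(subtree_leaves,
                          function(lf) lf[[j]]$value, 0))
    num <- num + w[[j]] * leafsum / root
  }
  unname(num / sum(w[keep]))
}

# Order candidates by (key1 desc, key2 desc, wmean desc, enumeration order).
# Enumeration order already encodes (feature order, ascending threshold /
# level order), giving the documented tie-breaks.
.mt_rank_scores <- function(scores) {
  key1 <- vapply(scores, `[[`, 0, "key1")
  key2 <- vapply(scores, `[[`, 0, "key2")
  wm <- vapply(scores, `[[`, 0, "wmean_prop_ig")
  keep <- which(is.finite(key1))
  keep[order(-key1[keep], -key2[keep], -wm[keep], keep)]
}

#' Select the winning split at a node
#'
#' Stepwise methods return the candidate with the best evalmethod aggregate
#' among those passing the complexity gate (weight-normalised mean
#' proportion IG `>= hp$cp`); ties go to the higher weighted mean proportion
#' IG, then earlier feature order, then lower threshold / earlier level.
#' With `evalmethod = "splitError"` the top `hp$parallelsplit` candidates by
#' immediate avgIG aggregate are each expanded into a depth-
#' `hp$paralleldepth` subtree grown with avgIG, and the candidate whose
#' subtree leaves retain the least multi-target error
#' ([lookahead_error()]) wins.
#'
#' @param candidates List from [enumerate_candidates()].
#' @param data Node-restricted `mt_dataset`.
#' @param hp An [mt_control].
#' @param node_losses Optional precomputed node losses.
#' @param used_features Features on the path (for lookahead recursion).
#' @return The winning `mt_split_candidate` with its `score` attached, or
#'   `NULL` (leaf signal).
#' @export
select_split <- function(candidates, data, hp = mt_control(),
                         node_losses = NULL, used_features = character()) {
  if (!length(candidates)) return(NULL)
  tv <- .mt_target_values(data)
  if (is.null(node_losses)) node_losses <- .mt_node_losses(tv)
  pv <- vapply(node_losses, `[[`, 0, "value")
  w <- vapply(tv, `[[`, 0, "w")
  if (!any(w > 0 & pv > 0)) return(NULL)  # nothing left to explain
  scores <- lapply(candidates, score_candidate, data = data, hp = hp,
                   node_losses = node_losses)
  wm <- vapply(scores, `[[`, 0, "wmean_prop_ig")

  if (hp$evalmethod == "splitError") {
    # Rank everything by immediate avgIG, lookahead on the top
    # `parallelsplit`, then apply the cp gate to the winner's immediate
    # aggregate.
    hp_rank <- hp; hp_rank$evalmethod <- "avgIG"
    rank_scores <- lapply(candidates, score_candidate, data = data,
                          hp = hp_rank, node_losses = node_losses)
    ord <- .mt_rank_scores(rank_scores)
    top <- ord[seq_len(min(hp$parallelsplit, length(ord)))]
    errs <- vapply(top, function(i) {
      .mt_candidate_lookahead_error(candidates[[i]], data, hp,
                                    node_losses, used_features)
    }, 0)
    win <- top[which.min(errs)]  # ties: earlier in avgIG ranking
    if (wm[win] < hp$cp) return(NULL)
    cand <- candidates[[win]]
    cand$score <- scores[[win]]
    cand$lookahead_error <- errs[[which(top == win)[1]]]
    return(cand)
  }

  pass <- which(wm >= hp$cp)
  if (!length(pass)) return(NULL)
  ord <- pass[.mt_rank_scores(scores[pass])]
  if (!length(ord)) return(NULL)  # e.g. no candidate significant (p methods)
  cand <- candidates[[ord[1]]]
  cand$score <- scores[[ord[1]]]
  cand
}

# Grow the depth-`paralleldepth` avgIG subtree under a forced candidate and
# return its multi-target lookahead error.
.mt_candidate_lookahead_error <- function(cand, data, hp, node_losses,
                                          used_features) {
  hp_sub <- hp
  hp_sub$evalmethod <- "avgIG"
  hp_sub$d <- hp$paralleldepth - 1L
  used2 <- if (hp$reuse) used_features else c(used_features, cand$feature)
  leaves <- list()
  for (rows in list(cand$left_rows, cand$right_rows)) {
    sub <- mt_subset(data, rows)
    leaves <- c(leaves, .mt_subtree_leaf_losses(sub, hp_sub, used2))
  }
  lookahead_error(leaves, node_losses, data$targets)
}

# Leaf losses of a small greedy subtree (operation-surface recursion; the
# fast engine has its own equivalent).
.mt_subtree_leaf_losses <- function(data, hp, used_features) {
  nl <- mt_node_losses(data)
  if (hp$d <= 0L || data$n_rows < hp$nodesize) return(list(nl))
  cands <- enumerate_candidates(data, hp, used_features)
  win <- select_split(cands, data, hp, nl, used_features)
  if (is.null(win)) return(list(nl))
  hp2 <- hp; hp2$d <- hp$d - 1L
  used2 <- if (hp$reuse) used_features else c(used_features, win$feature)
  c(.mt_subtree_leaf_losses(mt_subset(data, win$left_rows), hp2, used2),
    .mt_subtree_leaf_losses(mt_subset(data, win$right_rows), hp2, used2))
}
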