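# Vectorised split search. Scores every threshold of a feature in one pass
# from prefix sums over the sorted node rows (numeric features) or per-level
# group sums (categorical features), so growth cost per node is
# O(features * (n log n + cuts)) instead of O(candidates * n).
# Selection semantics are identical to select_split(); a property test
# pins the two routes together.

# One-off preparation of a dataset for repeated node-level work.
.mt_prep <- function(data) {
  df <- data$data
  tg <- lapply(data$targets, function(t) {
    y <- df[[t$name]]
    z <- list(name = t$name, type = t$type, w = t$weight)
    switch(t$type,
      continuous = { z$y <- y; z$y2 <- y^2 },
      categorical = {
        z$y <- y
        z$classes <- unique(y)
        z$yid <- match(y, z$classes)
        z$K <- length(z$classes)
      },
      count = {
        e <- if (!is.null(t$exposure)) df[[t$exposure]] else rep(1, nrow(df))
        z$y <- y; z$aux <- e; z$wle <- y * log(e)
      },
      survival = { z$y <- y; z$aux <- df[[t$event]] })
    z
  })
  list(df = df, targets = data$targets, tg = tg,
       feats = names(data$features), ftypes = data$features,
       flevels = data$feature_levels)
}

.mt_node_loss_prep <- function(z, rows) {
  node_loss_for(z, z$y[rows], if (is.null(z$aux)) NULL else z$aux[rows])
}

# Materialise the row sets of a chosen cut definition.
.mt_materialize <- function(prep, rows, def) {
  x <- prep$df[[def$feature]][rows]
  nm <- !is.na(x)
  lsel <- if (def$kind == "numeric_threshold") nm & x <= def$threshold
          else nm & x == def$level
  lrel <- which(lsel); rrel <- which(nm & !lsel); mrel <- which(!nm)
  side <- if (length(lrel) >= length(rrel)) "left" else "right"
  if (side == "left") lrel <- c(lrel, mrel) else rrel <- c(rrel, mrel)
  list(left = rows[sort(lrel)], right = rows[sort(rrel)],
       missing_side = side, n_missing = length(mrel))
}

# Full mt_split_score for the winning cut (stored in the tree).
.mt_winner_score <- function(prep, parent_losses, lrows, rrows, hp) {
  gains <- vector("list", length(prep$tg))
  for (j in seq_along(prep$tg)) {
    z <- prep$tg[[j]]
    gains[[j]] <- target_gain(parent_losses[[j]],
                              .mt_node_loss_prep(z, lrows),
                              .mt_node_loss_prep(z, rrows), z$type)
  }
  w <- vapply(prep$tg, `[[`, 0, "w")
  pv <- vapply(parent_losses, `[[`, 0, "value")
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

# Score all candidates of one feature. Returns NULL or a list of parallel
# vectors (thr/level, keys, wmean, n on each side, ...).
.mt_score_feature <- function(prep, rows, fi, hp, parent_losses, w, elig) {
  f <- prep$feats[fi]
  x <- prep$df[[f]][rows]
  misl <- is.na(x)
  n <- length(rows)
  n_mis <- sum(misl)
  rows_mis <- rows[misl]
  is_num <- prep$ftypes[[f]] == "numeric"

  if (is_num) {
    xs <- x[!misl]
    if (length(xs) < 2L) return(NULL)
    o <- order(xs)
    cuts <- .numeric_cuts(xs[o])
    if (!length(cuts$idx)) return(NULL)
    idx <- cuts$idx
    rsorted <- rows[!misl][o]
    Lsum <- function(v) cumsum(v[rsorted])[idx]
    nl0 <- idx
    nr0 <- length(xs) - nl0
    thr <- cuts$thr
    lev <- rep(NA_character_, length(idx))
  } else {
    xs <- x[!misl]
    lvls <- prep$flevels[[f]]
    lvls <- lvls[lvls %in% xs]
    if (length(lvls) < 2L) return(NULL)
    grp <- match(xs, lvls)
    rnm <- rows[!misl]
    ncand <- length(lvls)
    Lsum <- function(v) {
      s <- rowsum(v[rnm], grp)
      out <- numeric(ncand)
      out[as.integer(rownames(s))] <- s[, 1L]
      out
    }
    nl0 <- tabulate(grp, ncand)
    nr0 <- length(xs) - nl0
    thr <- rep(NA_real_, ncand)
    lev <- lvls
  }

  add <- as.numeric(nl0 >= nr0)          # missing rows join the larger side
  NL <- nl0 + n_mis * add
  NR <- n - NL
  keep <- NL >= hp$splitmin & NR >= hp$splitmin
  if (!any(keep)) return(NULL)
  msum <- function(v) if (n_mis) sum(v[rows_mis]) else 0

  m <- sum(elig)
  P <- matrix(0, length(NL), m)      # prop_ig per eligible target
  PV <- matrix(1, length(NL), m)     # p-value per eligible target
  col <- 0L
  xmin <- .Machine$double.xmin
  for (j in which(elig)) {
    z <- prep$tg[[j]]
    parent <- parent_losses[[j]]
    pval <- parent$value
    col <- col + 1L
    if (z$type == "continuous") {
      s1l <- Lsum(z$y) + add * msum(z$y)
      s2l <- Lsum(z$y2) + add * msum(z$y2)
      s1t <- parent$stats$mean * n
      s2t <- pval + s1t^2 / n
      lossL <- pmax(s2l - s1l^2 / NL, 0)
      lossR <- pmax((s2t - s2l) - (s1t - s1l)^2 / NR, 0)
      child <- lossL + lossR
      ig <- pval - child
      df2 <- n - 2L
      p <- if (df2 < 1L) rep(1, length(ig)) else {
        pp <- suppressWarnings(
          stats::pf(pmax(ig, 0) * df2 / child, 1, df2, lower.tail = FALSE))
        ifelse(child <= 0, ifelse(ig > 0, xmin, 1), pp)
      }
    } else if (z$type == "categorical") {
      cntP <- tabulate(z$yid[rows], z$K)
      CNTl <- vapply(seq_len(z$K), function(k) {
        v <- as.numeric(z$yid == k)
        Lsum(v) + add * msum(v)
      }, numeric(length(NL)))
      if (is.null(dim(CNTl))) CNTl <- matrix(CNTl, nrow = 1L)
      CNTr <- matrix(cntP, nrow(CNTl), z$K, byrow = TRUE) - CNTl
      lossL <- NL - rowSums(CNTl^2) / NL
      lossR <- NR - rowSums(CNTr^2) / NR
      ig <- pval - (lossL + lossR)
      present <- which(cntP > 0)
      if (length(present) < 2L) {
        p <- rep(1, length(ig))
      } else {
        pk <- cntP[present] / n
        el <- NL %o% pk
        er <- NR %o% pk
        stat <- rowSums((CNTl[, present, drop = FALSE] - el)^2 / el) +
                rowSums((CNTr[, present, drop = FALSE] - er)^2 / er)
        p <- stats::pchisq(stat, length(present) - 1L, lower.tail = FALSE)
      }
    } else if (z$type == "count") {
      Yl <- Lsum(z$y) + add * msum(z$y)
      El <- Lsum(z$aux) + add * msum(z$aux)
      Wl <- Lsum(z$wle) + add * msum(z$wle)
      Yt <- parent$stats$events; Et <- parent$stats$exposure
      Wt <- sum(z$wle[rows])
      Yr <- Yt - Yl; Er <- Et - El; Wr <- Wt - Wl
      lossL <- ifelse(Yl == 0, 0, -2 * (Wl + Yl * log(Yl / El) - Yl))
      lossR <- ifelse(Yr == 0, 0, -2 * (Wr + Yr * log(Yr / Er) - Yr))
      ig <- pval - (lossL + lossR)
      p <- stats::pchisq(pmax(ig, 0), 1, lower.tail = FALSE)
    } else {  # survival (times already cumulative-hazard scaled at the root)
      Dl <- Lsum(z$aux) + add * msum(z$aux)
      Tl <- Lsum(z$y) + add * msum(z$y)
      Dt <- parent$stats$events; Tt <- parent$stats$time
      Dr <- Dt - Dl; Tr <- Tt - Tl
      lamL <- Dl / pmax(Tl, xmin)
      lamR <- Dr / pmax(Tr, xmin)
      lossL <- ifelse(Dl == 0, 0, -2 * (Dl * log(lamL) - Dl))
      lossR <- ifelse(Dr == 0, 0, -2 * (Dr * log(lamR) - Dr))
      ig <- pval - (lossL + lossR)
      p <- stats::pchisq(pmax(ig, 0), 1, lower.tail = FALSE)
    }
    P[, col] <- if (pval <= 0) 0 else pmin(pmax(ig / pval, 0), 1)
    PV[, col] <- pmin(pmax(p, xmin), 1)
  }

  we <- w[elig]
  wmean <- as.vector(P %*% we) / sum(we)
  alpha <- hp$alpha
  n_sig <- rowSums(PV <= alpha)
  n_mean <- rowSums(P >= hp$IGcutoff)
  method <- hp$evalmethod
  if (method %in% c("avgIG", "splitError")) {
    key1 <- wmean; key2 <- rep(0, length(wmean))
  } else if (method == "maxIG") {
    key1 <- do.call(pmax, as.data.frame(P)); key2 <- rep(0, length(wmean))
  } else if (method == "mostIG") {
    key1 <- n_mean; key2 <- wmean
  } else if (method == "avgPVal") {
    sP <- rowSums(PV * (PV <= alpha))
    key1 <- -ifelse(n_sig > 0, sP / n_sig, Inf)
    key2 <- rep(0, length(wmean))
  } else if (method == "minPVal") {
    minp <- do.call(pmin, as.data.frame(PV))
    key1 <- -(minp / pmax(1, n_sig))
    key2 <- rep(0, length(wmean))
  } else {  # mostPVal
    sP <- rowSums(PV * (PV <= alpha))
    key1 <- n_sig
    key2 <- ifelse(n_sig > 0, -sP / n_sig, -Inf)
  }

  ki <- which(keep)
  list(feature = f, fi = fi,
       kind = if (is_num) "numeric_threshold" else "level_vs_rest",
       thr = thr[ki], lev = lev[ki], thrord = ki,
       key1 = key1[ki], key2 = key2[ki], wmean = wmean[ki])
}

# Fast equivalent of enumerate_candidates + select_split on absolute row
# indices. Returns NULL (leaf signal) or a winner with materialised row
# sets and an attached mt_split_score.
.mt_best_split <- function(prep, rows, hp, used_features, parent_losses) {
  w <- vapply(prep$tg, `[[`, 0, "w")
  pv <- vapply(parent_losses, `[[`, 0, "value")
  elig <- w > 0 & pv > 0
  if (!any(elig)) return(NULL)

  tabs <- list()
  for (fi in seq_along(prep$feats)) {
    if (!hp$reuse && prep$feats[fi] %in% used_features) next
    tab <- .mt_score_feature(prep, rows, fi, hp, parent_losses, w, elig)
    if (!is.null(tab)) tabs[[length(tabs) + 1L]] <- tab
  }
  if (!length(tabs)) return(NULL)

  cat_field <- function(nm) unlist(lapply(tabs, `[[`, nm), use.names = FALSE)
  key1 <- cat_field("key1"); key2 <- cat_field("key2")
  wmean <- cat_field("wmean")
  ford <- unlist(lapply(tabs, function(t) rep(t$fi, length(t$key1))))
  thrord <- cat_field("thrord")
  defs <- data.frame(
    feature = unlist(lapply(tabs, function(t) rep(t$feature, length(t$key1)))),
    kind = unlist(lapply(tabs, function(t) rep(t$kind, length(t$key1)))),
    thr = cat_field("thr"), lev = cat_field("lev"),
    stringsAsFactors = FALSE)

  finish <- function(i) {
    def <- list(feature = defs$feature[i], kind = defs$kind[i],
                threshold = defs$thr[i], level = defs$lev[i])
    mat <- .mt_materialize(prep, rows, def)
    score <- .mt_winner_score(prep, parent_losses, mat$left, mat$right, hp)
    c(def, mat, list(score = score))
  }

  if (hp$evalmethod == "splitError") {
    ord <- order(-key1, -key2, -wmean, ford, thrord)
    top <- ord[seq_len(min(hp$parallelsplit, length(ord)))]
    errs <- vapply(top, function(i) {
      def <- list(feature = defs$feature[i], kind = defs$kind[i],
                  threshold = defs$thr[i], level = defs$lev[i])
      mat <- .mt_materialize(prep, rows, def)
      .mt_lookahead_error_fast(prep, mat, def$feature, hp, used_features,
                               parent_losses, w)
    }, 0)
    win <- top[which.min(errs)]
    if (wmean[win] < hp$cp) return(NULL)
    out <- finish(win)
    out$lookahead_error <- min(errs)
    return(out)
  }

  pass <- which(wmean >= hp$cp & is.finite(key1))
  if (!length(pass)) return(NULL)
  ord <- pass[order(-key1[pass], -key2[pass], -wmean[pass],
                    ford[pass], thrord[pass])]
  # Analytically tied candidates (e.g. two features inducing the same
  # partition) can be ranked either way by prefix-sum rounding; re-score
  # the near-tied head with the exact per-candidate arithmetic so the
  # documented tie-breaks decide, identically to select_split().
  tol <- 1e-9 * max(1, abs(key1[ord[1L]]))
  head_ids <- ord[key1[ord] >= key1[ord[1L]] - tol]
  if (length(head_ids) > 1L) {
    exact <- lapply(head_ids, function(i) {
      def <- list(feature = defs$feature[i], kind = defs$kind[i],
                  threshold = defs$thr[i], level = defs$lev[i])
      mat <- .mt_materialize(prep, rows, def)
      .mt_winner_score(prep, parent_losses, mat$left, mat$right, hp)
    })
    k1 <- vapply(exact, `[[`, 0, "key1")
    k2 <- vapply(exact, `[[`, 0, "key2")
    wm <- vapply(exact, `[[`, 0, "wmean_prop_ig")
    ord <- head_ids[order(-k1, -k2, -wm, ford[head_ids],
                          thrord[head_ids])]
  }
  finish(ord[1L])
}

# Leaf loss-value matrix (targets x leaves) of an avgIG subtree grown under
# a forced split, then the normalised multi-target error.
.mt_lookahead_error_fast <- function(prep, mat, feature, hp, used_features,
                                     parent_losses, w) {
  hp_sub <- hp
  hp_sub$evalmethod <- "avgIG"
  hp_sub$d <- hp$paralleldepth - 1L
  used2 <- if (hp$reuse) used_features else c(used_features, feature)
  leaf_vals <- c(.mt_leaf_values_fast(prep, mat$left, hp_sub, used2, 0L),
                 .mt_leaf_values_fast(prep, mat$right, hp_sub, used2, 0L))
  keep <- w > 0
  num <- 0
  for (j in which(keep)) {
    root <- parent_losses[[j]]$value
    if (root <= 0) next
    num <- num + w[[j]] * sum(vapply(leaf_vals, `[`, 0, j)) / root
  }
  unname(num / sum(w[keep]))
}

.mt_leaf_values_fast <- function(prep, rows, hp, used_features, depth) {
  pl <- lapply(prep$tg, .mt_node_loss_prep, rows = rows)
  vals <- vapply(pl, `[[`, 0, "value")
  if (depth >= hp$d || length(rows) < hp$nodesize) return(list(vals))
  win <- .mt_best_split(prep, rows, hp, used_features, pl)
  if (is.null(win)) return(list(vals))
  used2 <- if (hp$reuse) used_features else c(used_features, win$feature)
  c(.mt_leaf_values_fast(prep, win$left, hp, used2, depth + 1L),
    .mt_leaf_values_fast(prep, win$right, hp, used2, depth + 1L))
}
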