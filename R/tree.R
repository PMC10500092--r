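#' Grow a multi-target decision tree
#'
#' Recursive partitioning from the root. A node is split while its depth is
#' below `control$d`, it holds at least `control$nodesize` rows, and the
#' configured evalmethod finds a candidate passing the complexity gate;
#' otherwise it becomes a leaf. Survival targets are rescaled once at the
#' root by their Nelson-Aalen cumulative hazard ([mt_surv_scale()]); the
#' scaling map is stored in the model so held-out evaluation happens on the
#' training scale. Growth is deterministic given `(data, targets, control)`.
#'
#' @param data An [mt_dataset].
#' @param targets Targets to model; defaults to `data$targets`.
#' @param control An [mt_control].
#' @return An object of class `mttree`: a flat, level-order-numbered node
#'   table plus target specs, control, feature schema and survival scaling
#'   maps.
#' @examples
#' sim <- mt_simulate(mt_plant_spec(n_rows = 200, n_noise_features = 2))
#' fit <- mt_grow(mt_dataset(sim$data, mt_sim_targets()),
#'                control = mt_control(d = 2))
#' print(fit)
#' @export
mt_grow <- function(data, targets = data$targets, control = mt_control()) {
  stopifnot(inherits(data, "mt_dataset"))
  if (!inherits(targets, "mt_targets")) targets <- mt_targets(targets)
  mt_check_weighted(targets)
  if (!identical(targets, data$targets)) data <- mt_dataset(data$data, targets)

  # Rescale survival times once at the root.
  surv_scales <- list()
  for (t in targets) {
    if (t$type == "survival") {
      map <- mt_surv_scale(data$data[[t$name]], data$data[[t$event]])
      surv_scales[[t$name]] <- map
      data$data[[t$name]] <- mt_surv_scale_apply(map, data$data[[t$name]])
    }
  }

  prep <- .mt_prep(data)
  nodes <- list()
  # BFS queue => level-order node ids.
  queue <- list(list(rows = seq_len(data$n_rows), depth = 0L,
                     used = character(), parent = NA_integer_))
  assign_leaf <- integer(data$n_rows)
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    id <- length(nodes) + 1L
    rows <- item$rows
    pl <- lapply(prep$tg, .mt_node_loss_prep, rows = rows)
    node <- list(id = id, depth = item$depth, n = length(rows),
                 parent = item$parent, is_leaf = TRUE,
                 split = NULL, children = NULL,
                 loss = lapply(pl, function(l) list(value = l$value, n = l$n)),
                 summary = .mt_leaf_summaries(prep, rows, pl),
                 score = NULL)
    win <- NULL
    if (item$depth < control$d && length(rows) >= control$nodesize)
      win <- .mt_best_split(prep, rows, control, item$used, pl)
    if (!is.null(win)) {
      node$is_leaf <- FALSE
      node$split <- list(feature = win$feature, kind = win$kind,
                         threshold = win$threshold, level = win$level,
                         missing_side = win$missing_side)
      sc <- win$score
      node$score <- list(
        aggregate = sc$aggregate,
        wmean_prop_ig = sc$wmean_prop_ig,
        n_significant = sc$n_significant,
        n_meaningful = sc$n_meaningful,
        prop_ig = vapply(sc$per_target, `[[`, 0, "prop_ig"),
        p_value = vapply(sc$per_target, `[[`, 0, "p_value"),
        ig = vapply(sc$per_target, `[[`, 0, "ig"))
      if (!is.null(win$lookahead_error))
        node$score$lookahead_error <- win$lookahead_error
      used2 <- if (control$reuse) item$used else c(item$used, win$feature)
      queue <- c(queue, list(
        list(rows = win$left, depth = item$depth + 1L, used = used2,
             parent = id),
        list(rows = win$right, depth = item$depth + 1L, used = used2,
             parent = id)))
      node$pending_children <- TRUE
    } else {
      assign_leaf[rows] <- id
    }
    nodes[[id]] <- node
  }
  # Wire children: BFS order guarantees each parent precedes its children;
  # match children to parents by the stored parent id.
  for (id in seq_along(nodes)) {
    ch <- which(vapply(nodes, function(nd)
      identical(nd$parent, id), TRUE))
    if (length(ch)) nodes[[id]]$children <- as.integer(ch)
    nodes[[id]]$pending_children <- NULL
    nodes[[id]]$parent <- NULL
  }

  structure(list(
    schema = "mttree/1",
    nodes = nodes,
    targets = targets,
    control = control,
    feature_info = list(names = names(data$features),
                        types = data$features,
                        levels = data$feature_levels),
    surv_scales = surv_scales,
    train_n = data$n_rows,
    train_leaf = assign_leaf
  ), class = "mttree")
}

# Per-target leaf summaries from already-computed node losses.
.mt_leaf_summaries <- function(prep, rows, pl) {
  lapply(seq_along(prep$tg), function(j) {
    z <- prep$tg[[j]]
    st <- pl[[j]]$stats
    switch(z$type,
      continuous = list(mean = st$mean, n = pl[[j]]$n),
      categorical = {
        cnt <- tabulate(z$yid[rows], z$K)
        prop <- cnt / sum(cnt)
        names(prop) <- z$classes
        list(modal = z$classes[which.max(cnt)], prop = prop)
      },
      count = list(rate = st$rate, exposure = st$exposure),
      survival = list(rate = st$rate, events = st$events))
  })
}

#' @export
print.mttree <- function(x, ...) {
  cat(mt_render_text(x), sep = "\n")
  invisible(x)
}

#' Number of leaves of a tree
#' @param model An `mttree`.
#' @return Integer leaf count.
#' @export
mt_n_leaves <- function(model) {
  sum(vapply(model$nodes, `[[`, TRUE, "is_leaf"))
}

# Route a data frame of features through the tree; returns the leaf id per
# row. Unseen categorical levels go to the "rest" side; missing values
# follow the training-time majority side stored on each split node.
.mt_route <- function(model, df) {
  need <- model$feature_info$names
  miss <- setdiff(unique(vapply(model$nodes[!vapply(model$nodes, `[[`, TRUE,
                                                    "is_leaf")],
                                function(nd) nd$split$feature, "")),
                  names(df))
  if (length(miss))
    mt_stop_config(sprintf("missing required feature column(s): %s",
                           paste(miss, collapse = ", ")))
  n <- nrow(df)
  leaf <- integer(n)
  at <- rep(1L, n)
  active <- seq_len(n)
  n_unseen <- 0L
  while (length(active)) {
    ids <- unique(at[active])
    nxt_active <- integer(0)
    for (id in ids) {
      nd <- model$nodes[[id]]
      here <- active[at[active] == id]
      if (nd$is_leaf) { leaf[here] <- id; next }
      sp <- nd$split
      x <- df[[sp$feature]][here]
      if (sp$kind == "numeric_threshold") {
        go_left <- x <= sp$threshold
      } else {
        lv <- model$feature_info$levels[[sp$feature]]
        n_unseen <- n_unseen + sum(!is.na(x) & !(x %in% lv))
        go_left <- !is.na(x) & x == sp$level
      }
      go_left[is.na(x)] <- sp$missing_side == "left"
      at[here] <- ifelse(go_left, nd$children[1], nd$children[2])
      nxt_active <- c(nxt_active, here)
    }
    active <- nxt_active
  }
  if (n_unseen > 0)
    message(sprintf(
      "mttree: %d value(s) at unseen categorical levels routed to 'rest'",
      n_unseen))
  leaf
}

#' Predict endpoints with a multi-target tree
#'
#' Routes each row to a leaf and returns the training leaf summaries as
#' predictions: the leaf mean (continuous), the modal level (categorical),
#' and the leaf event rate (count; survival on the training
#' cumulative-hazard scale). Rows with missing split-feature values follow
#' the side the training majority took; unseen categorical levels are
#' routed to the "rest" side of level-vs-rest splits.
#'
#' @param object An `mttree`.
#' @param newdata A data frame (or `mt_dataset`) holding the training
#'   feature columns.
#' @param ... Unused.
#' @return A data frame with one prediction column per target plus a
#'   `.leaf` column of leaf node ids.
#' @export
predict.mttree <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "mt_dataset")) newdata$data else
    as.data.frame(newdata, stringsAsFactors = FALSE)
  leaf <- .mt_route(object, df)
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (j in seq_along(object$targets)) {
    t <- object$targets[[j]]
    vals <- vapply(object$nodes, function(nd) {
      s <- nd$summary[[j]]
      switch(t$type, continuous = s$mean, categorical = NA_real_,
             count = s$rate, survival = s$rate)
    }, 0)
    if (t$type == "categorical") {
      labs <- vapply(object$nodes, function(nd) nd$summary[[j]]$modal, "")
      out[[t$name]] <- labs[leaf]
    } else {
      out[[t$name]] <- vals[leaf]
    }
  }
  out$.leaf <- leaf
  out
}

#' Evaluate a tree on (held-out) data
#'
#' Routes `data` through the model and reports, per target, a predictive
#' loss computed with the *training* leaf parameters, plus the
#' weight-normalised overall error
#' `sum_t w_t (loss_t / root_loss_t) / sum_t w_t`, where `root_loss_t` is
#' the same plug-in loss under the model's root (single-leaf) parameters.
#' A single-leaf model therefore scores exactly 1, and a tree that is pure
#' on the evaluation data scores 0. Per-target display metrics: RMSE and
#' R-squared (continuous; R-squared is `NA` when the evaluation data has
#' zero variance), accuracy and size-weighted Gini of predicted-leaf
#' memberships (categorical), mean Poisson deviance per row (count), mean
#' exponential deviance per row (survival, on the training time scale).
#'
#' @param model An `mttree`.
#' @param data An [mt_dataset] including target columns.
#' @param targets Defaults to the model's targets.
#' @return An `mt_eval` with `per_target`, `overall`, `n_leaves`, and
#'   `leaf_assignment`.
#' @export
mt_evaluate <- function(model, data, targets = model$targets) {
  stopifnot(inherits(model, "mttree"), inherits(data, "mt_dataset"))
  df <- data$data
  leaf <- .mt_route(model, df)
  root <- model$nodes[[1]]
  floor_mu <- 1e-8
  per <- list()
  ratios <- numeric(length(targets))
  for (j in seq_along(targets)) {
    t <- targets[[j]]
    y <- df[[t$name]]
    sum_leaf <- function(id) model$nodes[[id]]$summary[[j]]
    if (t$type == "continuous") {
      mu <- vapply(leaf, function(id) sum_leaf(id)$mean, 0)
      dev <- sum((y - mu)^2)
      dev0 <- sum((y - root$summary[[j]]$mean)^2)
      sst <- sum((y - mean(y))^2)
      per[[t$name]] <- list(
        type = t$type, loss = dev, root_loss = dev0,
        rmse = sqrt(dev / length(y)),
        r_squared = if (sst > 0) 1 - dev / sst else NA_real_)
    } else if (t$type == "categorical") {
      classes <- names(root$summary[[j]]$prop)
      brier <- function(ids) {
        tot <- 0
        for (id in unique(ids)) {
          pr <- sum_leaf(id)$prop
          yy <- y[ids == id]
          ind_sq <- sum(pr^2)
          py <- ifelse(yy %in% names(pr), pr[yy], 0)
          tot <- tot + sum(1 - 2 * py + ind_sq)
        }
        tot
      }
      dev <- brier(leaf)
      dev0 <- brier(rep(1L, length(y)))
      pred <- vapply(leaf, function(id) sum_leaf(id)$modal, "")
      gini <- sum(vapply(unique(leaf), function(id) {
        yy <- y[leaf == id]
        cnt <- table(yy)
        length(yy) - sum(cnt^2) / length(yy)
      }, 0))
      per[[t$name]] <- list(
        type = t$type, loss = dev, root_loss = dev0,
        accuracy = mean(pred == y), gini = gini)
    } else if (t$type == "count") {
      e <- if (!is.null(t$exposure)) df[[t$exposure]] else rep(1, length(y))
      pois_dev <- function(lam) {
        mu <- pmax(lam * e, floor_mu)
        sum(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
      }
      lam_leaf <- vapply(leaf, function(id) sum_leaf(id)$rate, 0)
      dev <- {
        mu <- pmax(lam_leaf * e, floor_mu)
        sum(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
      }
      dev0 <- pois_dev(root$summary[[j]]$rate)
      per[[t$name]] <- list(type = t$type, loss = dev, root_loss = dev0,
                            mean_deviance = dev / length(y))
    } else {  # survival: evaluate on the training cumulative-hazard scale
      map <- model$surv_scales[[t$name]]
      tt <- mt_surv_scale_apply(map, y)
      ev <- df[[t$event]]
      exp_dev <- function(lam) {
        mu <- pmax(lam * tt, floor_mu)
        sum(2 * (ifelse(ev > 0, -log(mu) - 1 + mu, mu)))
      }
      lam_leaf <- vapply(leaf, function(id) sum_leaf(id)$rate, 0)
      dev <- {
        mu <- pmax(lam_leaf * tt, floor_mu)
        sum(2 * (ifelse(ev > 0, -log(mu) - 1 + mu, mu)))
      }
      dev0 <- exp_dev(root$summary[[j]]$rate)
      per[[t$name]] <- list(type = t$type, loss = dev, root_loss = dev0,
                            mean_deviance = dev / length(y))
    }
    ratios[j] <- if (per[[t$name]]$root_loss > 0)
      per[[t$name]]$loss / per[[t$name]]$root_loss else 0
  }
  w <- vapply(targets, `[[`, 0, "weight")
  keep <- w > 0
  overall <- sum(w[keep] * ratios[keep]) / sum(w[keep])
  structure(list(per_target = per, overall = overall,
                 n_leaves = mt_n_leaves(model),
                 leaf_assignment = leaf),
            class = "mt_eval")
}

#' @export
print.mt_eval <- function(x, ...) {
  cat(sprintf("Multi-target evaluation: overall error %.4f (%d leaves)\n",
              x$overall, x$n_leaves))
  for (nm in names(x$per_target)) {
    pt <- x$per_target[[nm]]
    extra <- switch(pt$type,
      continuous = sprintf("rmse=%.4g, R2=%s", pt$rmse,
                           if (is.na(pt$r_squared)) "NA"
                           else sprintf("%.3f", pt$r_squared)),
      categorical = sprintf("accuracy=%.3f", pt$accuracy),
      sprintf("mean deviance=%.4g", pt$mean_deviance))
    cat(sprintf("  %s (%s): loss=%.4g / root=%.4g, %s\n",
                nm, pt$type, pt$loss, pt$root_loss, extra))
  }
  invisible(x)
}
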