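# Node losses per outcome type. All four are chosen so that
# parent - (left + right) is the canonical single-target split criterion:
#   continuous  : within-node sum of squares        -> variance reduction
#   categorical : n * Gini impurity                 -> size-weighted Gini gain
#   count       : -2 log-likelihood at the node MLE -> Poisson LR statistic
#   survival    : -2 log-likelihood at the node MLE -> exponential LR statistic
# The y!-terms (count) and the Sum(y_i log E_i) term are omitted: they are
# constant over any partition of the same rows, so every gain is unchanged.

new_node_loss <- function(value, n, stats) {
  structure(list(value = value, n = n, stats = stats), class = "mt_node_loss")
}

#' Continuous node loss (deviance)
#'
#' Within-node sum of squared deviations from the node mean.
#'
#' @param values Numeric vector, length >= 1.
#' @return An `mt_node_loss` with fields `value`, `n`, `stats`.
#' @export
node_loss_continuous <- function(values) {
  if (!length(values)) mt_stop_domain("empty node: continuous loss undefined")
  m <- mean(values)
  new_node_loss(sum((values - m)^2), length(values), list(mean = m))
}

#' Categorical node loss (size-weighted Gini)
#'
#' `n * (1 - sum(p_k^2))` over the within-node class proportions.
#'
#' @param labels Vector of class labels, length >= 1.
#' @return An `mt_node_loss`; `stats$counts` holds the class counts.
#' @export
node_loss_categorical <- function(labels) {
  if (!length(labels)) mt_stop_domain("empty node: categorical loss undefined")
  labels <- as.character(labels)
  cnt <- table(labels)
  n <- length(labels)
  cnt <- c(cnt)  # named integer vector
  new_node_loss(n - sum(cnt^2) / n, n, list(counts = cnt))
}

#' Count node loss (-2 Poisson log-likelihood at the node rate MLE)
#'
#' With rate MLE `lambda = sum(y)/sum(E)`:
#' `value = -2 * sum(y_i log(lambda E_i) - lambda E_i)`, with `0 log 0 = 0`.
#'
#' @param counts Non-negative integer vector.
#' @param exposure Positive exposures, recycled unit exposure when `NULL`.
#' @return An `mt_node_loss`; `stats` holds total events, exposure, rate.
#' @export
node_loss_count <- function(counts, exposure = NULL) {
  if (!length(counts)) mt_stop_domain("empty node: count loss undefined")
  if (is.null(exposure)) exposure <- rep(1, length(counts))
  if (length(exposure) != length(counts))
    mt_stop_domain("counts and exposure lengths differ")
  if (any(exposure <= 0)) mt_stop_domain("exposures must be positive")
  Y <- sum(counts); E <- sum(exposure)
  lam <- Y / E
  value <- if (Y == 0) 0 else {
    term <- ifelse(counts > 0, counts * log(lam * exposure), 0)
    -2 * (sum(term) - lam * E)
  }
  new_node_loss(value, length(counts),
                list(events = Y, exposure = E, rate = lam))
}

#' Survival node loss (-2 exponential log-likelihood at the node rate MLE)
#'
#' With `D = sum(events)`, `T = sum(times)` and `lambda = D/T`:
#' `value = -2 * (D log(lambda) - lambda T)`; by convention the loss is 0
#' when no events occurred. Intended to be used on cumulative-hazard-scaled
#' times (see [mt_surv_scale()]), which makes the constant-hazard model exact
#' at the scaling node.
#'
#' @param times Non-negative survival times.
#' @param events 0/1 event indicators.
#' @return An `mt_node_loss`; `stats` holds events, total time, rate.
#' @export
node_loss_survival <- function(times, events) {
  if (!length(times)) mt_stop_domain("empty node: survival loss undefined")
  if (length(times) != length(events))
    mt_stop_domain("times and events lengths differ")
  D <- sum(events); Tt <- sum(times)
  if (D == 0)
    return(new_node_loss(0, length(times),
                         list(events = 0, time = Tt, rate = 0)))
  if (Tt <= 0) mt_stop_domain("total survival time is zero with events present")
  lam <- D / Tt
  new_node_loss(-2 * (D * log(lam) - lam * Tt), length(times),
                list(events = D, time = Tt, rate = lam))
}

node_loss_for <- function(tgt, y, aux) {
  switch(tgt$type,
    continuous = node_loss_continuous(y),
    categorical = node_loss_categorical(y),
    count = node_loss_count(y, aux),
    survival = node_loss_survival(y, aux))
}

.clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

#' Per-target gain of a binary split
#'
#' Raw information gain (parent loss minus summed child losses), the
#' standardized proportion IG (fraction of the parent loss explained,
#' clipped to `[0,1]`, defined as 0 for a pure parent), and a per-type
#' split p-value: one-way ANOVA F for continuous, chi-square independence
#' on the 2 x K split-by-class table for categorical, and chi-square with
#' 1 df on the likelihood-ratio statistic for count and survival.
#'
#' @param parent,left,right `mt_node_loss` objects for the same target.
#' @param ttype Target type, one of the four outcome types.
#' @return List with `ig`, `prop_ig`, `p_value`, `df` (class `mt_target_gain`).
#' @export
target_gain <- function(parent, left, right, ttype) {
  if (parent$n != left$n + right$n)
    mt_stop_internal("child row counts do not sum to the parent count")
  ig <- parent$value - (left$value + right$value)
  prop_ig <- if (parent$value <= 0) 0 else min(max(ig / parent$value, 0), 1)
  child <- left$value + right$value
  if (ttype == "continuous") {
    df2 <- parent$n - 2L
    p <- if (df2 < 1L) 1 else if (child <= 0) {
      if (ig > 0) .Machine$double.xmin else 1
    } else stats::pf(max(ig, 0) * df2 / child, 1, df2, lower.tail = FALSE)
    dfree <- 1L
  } else if (ttype == "categorical") {
    cl <- left$stats$counts; cr <- right$stats$counts
    classes <- union(names(cl), names(cr))
    ol <- ifelse(classes %in% names(cl), cl[classes], 0)
    or <- ifelse(classes %in% names(cr), cr[classes], 0)
    tot <- ol + or
    keep <- tot > 0
    ol <- ol[keep]; or <- or[keep]; tot <- tot[keep]
    K <- length(tot)
    if (K < 2L) {
      p <- 1; dfree <- 1L
    } else {
      n <- parent$n; nl <- left$n; nr <- right$n
      el <- nl * tot / n; er <- nr * tot / n
      stat <- sum((ol - el)^2 / el) + sum((or - er)^2 / er)
      dfree <- K - 1L
      p <- stats::pchisq(stat, dfree, lower.tail = FALSE)
    }
  } else {  # count, survival: LR statistic ~ chi-square(1)
    dfree <- 1L
    p <- stats::pchisq(max(ig, 0), 1, lower.tail = FALSE)
  }
  structure(list(ig = ig, prop_ig = prop_ig, p_value = .clamp_p(p),
                 df = dfree),
            class = "mt_target_gain")
}

#' Nelson-Aalen cumulative-hazard time scaling
#'
#' Fits the Nelson-Aalen estimator on `(times, events)` and returns a step
#' map replacing each time by its estimated cumulative hazard. Applied once
#' at the root before growth, this makes the unit-rate exponential model
#' exact at the root (total scaled time equals total events), so exponential
#' likelihood-ratio split tests are well calibrated.
#'
#' @param times Non-negative times.
#' @param events 0/1 event indicators.
#' @return An `mt_surv_scale` map with `times` (distinct event times) and
#'   `haz` (cumulative hazard at each).
#' @export
mt_surv_scale <- function(times, events) {
  stopifnot(length(times) == length(events))
  et <- sort(unique(times[events == 1]))
  if (!length(et))
    return(structure(list(times = numeric(0), haz = numeric(0)),
                     class = "mt_surv_scale"))
  d <- vapply(et, function(tj) sum(times == tj & events == 1), 0)
  n_at_risk <- vapply(et, function(tj) sum(times >= tj), 0)
  structure(list(times = et, haz = cumsum(d / n_at_risk)),
            class = "mt_surv_scale")
}

#' Apply a cumulative-hazard scaling map
#'
#' @param map An `mt_surv_scale` object.
#' @param times Times to rescale.
#' @return Scaled times (cumulative hazard at each input time).
#' @export
mt_surv_scale_apply <- function(map, times) {
  stopifnot(inherits(map, "mt_surv_scale"))
  if (!length(map$times)) return(rep(0, length(times)))
  idx <- findInterval(times, map$times)
  c(0, map$haz)[idx + 1L]
}
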