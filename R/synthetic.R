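#' Specification for planted-subgroup synthetic data
#'
#' Describes a depth-2 ground-truth partition: two planted uniform(0,1)
#' features cut at stated thresholds define four subgroups (quadrants), and
#' each subgroup has its own parameters for all four outcome types. The
#' defaults emulate a strongly separable molecular cohort: adjacent
#' continuous subgroup means at least 2 residual standard deviations apart,
#' event rates at least 2-fold apart, 30% survival censoring.
#'
#' @param n_rows Number of rows.
#' @param n_noise_features Number of independent uniform(0,1) noise features.
#' @param planted Named numeric vector of two planted feature thresholds.
#' @param cont_means Per-subgroup continuous means (residual sd is 1).
#' @param cat_probs 4 x L matrix of per-subgroup categorical level
#'   probabilities (rows sum to 1).
#' @param cat_levels Categorical level labels.
#' @param count_rates Per-subgroup Poisson rates (unit exposure).
#' @param surv_rates Per-subgroup exponential event rates.
#' @param censor_frac Expected fraction of censored survival rows, in
#'   `[0, 1)`; censoring is independent uniform(0, c) with `c` solved
#'   numerically.
#' @param seed Integer seed; generation is byte-deterministic given it.
#' @return An `mt_plant_spec`.
#' @export
mt_plant_spec <- function(n_rows = 1000L, n_noise_features = 20L,
                          planted = c(x1 = 0.5, x2 = 0.5),
                          cont_means = c(0, 3, 6, 9),
                          cat_probs = rbind(c(0.8, 0.1, 0.1),
                                            c(0.1, 0.8, 0.1),
                                            c(0.1, 0.1, 0.8),
                                            c(0.6, 0.2, 0.2)),
                          cat_levels = c("A", "B", "C"),
                          count_rates = c(1, 2, 4, 8),
                          surv_rates = c(0.5, 1, 2, 4),
                          censor_frac = 0.3, seed = 1L) {
  if (length(planted) != 2L || is.null(names(planted)) ||
      any(planted <= 0 | planted >= 1))
    mt_stop_config("'planted' must name two thresholds strictly inside (0,1)")
  if (length(cont_means) != 4L || length(count_rates) != 4L ||
      length(surv_rates) != 4L || nrow(cat_probs) != 4L)
    mt_stop_config("per-subgroup parameters must have 4 entries (quadrants)")
  # Duplicated values merge quadrants into 3 (or 2) effective subgroups;
  # the separability floor applies to the distinct values.
  if (any(diff(sort(unique(cont_means))) < 2))
    mt_stop_config("adjacent continuous subgroup means must differ by >= 2 sd")
  chk_rates <- function(r, nm) {
    r <- sort(unique(r))
    if (any(r <= 0) || (length(r) > 1 && any(r[-1] / r[-length(r)] < 2)))
      mt_stop_config(sprintf(
        "'%s' must be positive and pairwise >= 2-fold apart", nm))
  }
  chk_rates(count_rates, "count_rates")
  chk_rates(surv_rates, "surv_rates")
  if (ncol(cat_probs) != length(cat_levels) ||
      any(abs(rowSums(cat_probs) - 1) > 1e-9) || any(cat_probs < 0))
    mt_stop_config("'cat_probs' rows must be probability vectors over levels")
  if (!is.numeric(censor_frac) || censor_frac < 0 || censor_frac >= 1)
    mt_stop_config("'censor_frac' must lie in [0, 1)")
  structure(list(n_rows = as.integer(n_rows),
                 n_noise_features = as.integer(n_noise_features),
                 planted = planted, cont_means = cont_means,
                 cat_probs = cat_probs, cat_levels = cat_levels,
                 count_rates = count_rates, surv_rates = surv_rates,
                 censor_frac = censor_frac, seed = as.integer(seed)),
            class = "mt_plant_spec")
}

#' Target declaration matching [mt_simulate()] output
#'
#' @param weights Optional numeric vector of four weights
#'   (continuous, categorical, count, survival order).
#' @return An [mt_targets] for columns `y_cont`, `y_cat`, `y_count`,
#'   `y_time`/`y_event`.
#' @export
mt_sim_targets <- function(weights = c(1, 1, 1, 1)) {
  mt_targets(
    mt_target("y_cont", "continuous", weights[1]),
    mt_target("y_cat", "categorical", weights[2]),
    mt_target("y_count", "count", weights[3]),
    mt_target("y_time", "survival", weights[4], event = "y_event"))
}

# Upper censoring bound c such that E[fraction censored] = frac under
# T ~ Exp(rate_g), C ~ Uniform(0, c), subgroups equally likely.
.mt_censor_bound <- function(rates, frac) {
  if (frac == 0) return(Inf)
  f <- function(cc) mean((1 - exp(-rates * cc)) / (rates * cc)) - frac
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
}

#' Generate a planted-subgroup multi-target dataset
#'
#' Planted and noise features are independent uniform(0,1); the two planted
#' thresholds define four ground-truth subgroups, and each target is drawn
#' from its subgroup's distribution: Normal(mean, 1), the stated categorical
#' distribution, Poisson(rate), and Exponential(rate) with independent
#' uniform censoring hitting the stated censoring fraction in expectation.
#'
#' @param spec An [mt_plant_spec].
#' @return List with `data` (a data frame: planted features, noise features
#'   `z1..zk`, and `y_cont`, `y_cat`, `y_count`, `y_time`, `y_event`),
#'   `truth` (integer subgroup labels 1-4, a deterministic function of the
#'   planted features), and `spec`.
#' @export
mt_simulate <- function(spec = mt_plant_spec()) {
  stopifnot(inherits(spec, "mt_plant_spec"))
  n <- spec$n_rows
  with_mt_seed(spec$seed, {
    f1 <- stats::runif(n); f2 <- stats::runif(n)
    g <- 1L + 2L * (f1 > spec$planted[1]) + 1L * (f2 > spec$planted[2])
    df <- data.frame(f1, f2)
    names(df) <- names(spec$planted)
    if (spec$n_noise_features > 0) {
      for (i in seq_len(spec$n_noise_features))
        df[[paste0("z", i)]] <- stats::runif(n)
    }
    df$y_cont <- stats::rnorm(n, spec$cont_means[g], 1)
    y_cat <- character(n)
    for (gi in 1:4) {
      idx <- which(g == gi)
      if (length(idx))
        y_cat[idx] <- sample(spec$cat_levels, length(idx), replace = TRUE,
                             prob = spec$cat_probs[gi, ])
    }
    df$y_cat <- y_cat
    df$y_count <- stats::rpois(n, spec$count_rates[g])
    tt <- stats::rexp(n, spec$surv_rates[g])
    if (spec$censor_frac > 0) {
      cc <- .mt_censor_bound(spec$surv_rates, spec$censor_frac)
      cens <- stats::runif(n, 0, cc)
      df$y_time <- pmin(tt, cens)
      df$y_event <- as.numeric(tt <= cens)
    } else {
      df$y_time <- tt
      df$y_event <- rep(1, n)
    }
    list(data = df, truth = g, spec = spec)
  })
}
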