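# Candidate enumeration, scoring, selection, and the lookahead.

one_target_data <- function(df, yname = "y") {
  mt_dataset(df, mt_targets(mt_target(yname, "continuous")))
}

test_that("numeric thresholds are midpoints of consecutive distinct values", {
  d <- one_target_data(data.frame(x = c(1, 2, 4), y = c(0, 0, 1)))
  cands <- enumerate_candidates(d, mt_control(splitmin = 1))
  thr <- vapply(cands, `[[`, 0, "threshold")
  expect_equal(thr, c(1.5, 3.0))
  expect_equal(cands[[1]]$left_rows, 1L)
  expect_equal(sort(cands[[1]]$right_rows), c(2L, 3L))
})

test_that("categorical features give one level-vs-rest candidate per level", {
  d <- one_target_data(data.frame(g = c("X", "Y", "Z", "X"),
                                  y = c(1, 2, 3, 4)))
  cands <- enumerate_candidates(d, mt_control(splitmin = 1))
  expect_length(cands, 3L)
  expect_equal(vapply(cands, `[[`, "", "level"), c("X", "Y", "Z"))
  expect_equal(vapply(cands, `[[`, "", "kind"),
               rep("level_vs_rest", 3))
  expect_equal(sort(cands[[1]]$left_rows), c(1L, 4L))
})

test_that("splitmin prunes infeasible candidates", {
  d <- one_target_data(data.frame(x = 1:10, y = stats::rnorm(10)))
  expect_length(enumerate_candidates(d, mt_control(splitmin = 7)), 0L)
  expect_length(enumerate_candidates(d, mt_control(splitmin = 5)), 1L)
})

test_that("reuse = FALSE skips features already on the path", {
  d <- one_target_data(data.frame(x = 1:10, z = 10:1, y = stats::rnorm(10)))
  hp <- mt_control(splitmin = 2, reuse = FALSE)
  cands <- enumerate_candidates(d, hp, used_features = "x")
  expect_true(all(vapply(cands, `[[`, "", "feature") == "z"))
})

test_that("missing feature values go to the larger side and count in checks", {
  df <- data.frame(x = c(1, 2, 3, 4, 5, NA, NA), y = stats::rnorm(7))
  d <- one_target_data(df)
  cands <- enumerate_candidates(d, mt_control(splitmin = 1))
  # threshold 1.5: left {1}, right {2..5} + missing (larger side)
  c1 <- cands[[1]]
  expect_equal(c1$threshold, 1.5)
  expect_equal(c1$missing_side, "right")
  expect_equal(sort(c1$right_rows), c(2L, 3L, 4L, 5L, 6L, 7L))
  # threshold 4.5: left {1..4} larger, takes the missing rows
  c4 <- cands[[4]]
  expect_equal(c4$missing_side, "left")
  expect_equal(sort(c4$left_rows), c(1L, 2L, 3L, 4L, 6L, 7L))
})

test_that("avgIG aggregates weight-normalised mean proportion IG", {
  # two targets engineered to give prop_ig (1, 0): y1 perfectly split,
  # y2 identical on both sides
  df <- data.frame(x = c(1, 1, 2, 2),
                   y1 = c(0, 0, 4, 4), y2 = c(1, 5, 1, 5))
  ts <- mt_targets(mt_target("y1", "continuous"),
                   mt_target("y2", "continuous"))
  d <- mt_dataset(df, ts)
  cand <- enumerate_candidates(d, mt_control(splitmin = 1))[[1]]
  sc <- score_candidate(cand, d, mt_control(splitmin = 1))
  expect_equal(vapply(sc$per_target, `[[`, 0, "prop_ig"), c(1, 0))
  expect_equal(sc$aggregate, 0.5)
  # zero-weight target is excluded
  ts0 <- mt_targets(mt_target("y1", "continuous", weight = 1),
                    mt_target("y2", "continuous", weight = 0))
  d0 <- mt_dataset(df, ts0)
  sc0 <- score_candidate(cand, d0, mt_control(splitmin = 1))
  expect_equal(sc0$aggregate, 1.0)
})

test_that("mostPVal counts significant targets first", {
  # three candidates on a toy node; the one significant on 2 targets must
  # beat any candidate significant on 1, whatever its minimum p
  set.seed(42)
  n <- 40
  g <- rep(c(0, 1), each = n / 2)
  df <- data.frame(
    a = g + stats::runif(n, 0, 0.1),         # splits y1 and y2
    b = rep(c(0, 1), n / 2) + stats::runif(n, 0, 0.1),  # splits y3 only
    y1 = stats::rnorm(n, 2 * g),
    y2 = stats::rnorm(n, 2 * g),
    y3 = stats::rnorm(n, 8 * rep(c(0, 1), n / 2)))
  ts <- mt_targets(mt_target("y1", "continuous"),
                   mt_target("y2", "continuous"),
                   mt_target("y3", "continuous"))
  d <- mt_dataset(df, ts)
  hp <- mt_control(evalmethod = "mostPVal", splitmin = 5, cp = 0)
  cands <- enumerate_candidates(d, hp)
  scores <- lapply(cands, score_candidate, data = d, hp = hp)
  nsig <- vapply(scores, `[[`, 0L, "n_significant")
  win <- select_split(cands, d, hp)
  expect_equal(win$score$n_significant, max(nsig))
  expect_gte(win$score$n_significant, 2L)
  expect_equal(win$feature, "a")
  # exhaustive check: no candidate with more significant targets exists
  expect_true(all(nsig <= win$score$n_significant))
})

test_that("cp gates weak splits and ties break toward lower thresholds", {
  # aggregate below cp => leaf signal
  set.seed(1)
  df <- data.frame(x = stats::runif(20), y = stats::rnorm(20))
  d <- one_target_data(df)
  hp <- mt_control(cp = 0.999, splitmin = 2)
  expect_null(select_split(enumerate_candidates(d, hp), d, hp))
  # duplicated feature values => identical aggregates; lower threshold wins
  df2 <- data.frame(x = c(1, 2, 3, 1, 2, 3), y = c(0, 5, 5, 0, 5, 5))
  d2 <- one_target_data(df2)
  hp2 <- mt_control(splitmin = 2, cp = 0)
  win <- select_split(enumerate_candidates(d2, hp2), d2, hp2)
  expect_equal(win$threshold, 1.5)
})

test_that("alpha-monotonicity: smaller alpha never raises n_significant", {
  set.seed(9)
  for (rep in 1:5) {
    d <- random_mtdata(30)
    cands <- enumerate_candidates(d, mt_control(splitmin = 3))
    alphas <- c(0.2, 0.1, 0.05, 0.01)
    for (cand in cands[seq_len(min(5, length(cands)))]) {
      ns <- vapply(alphas, function(a) {
        hp <- mt_control(splitmin = 3, alpha = a)
        score_candidate(cand, d, hp)$n_significant
      }, 0L)
      expect_true(all(diff(ns) <= 0))
    }
  }
})

test_that("fast engine and operation surface select identical splits", {
  set.seed(17)
  for (rep in 1:12) {
    method <- MT_EVAL_METHODS[(rep - 1) %% 7 + 1]
    d <- random_mtdata(sample(25:45, 1), n_num = 2, n_cat = 1,
                       na_frac = ifelse(rep %% 3 == 0, 0.1, 0))
    hp <- mt_control(evalmethod = method, splitmin = 3, nodesize = 10,
                     cp = 0.005, parallelsplit = 3, paralleldepth = 1)
    surface <- select_split(enumerate_candidates(d, hp), d, hp)
    prep <- mttree:::.mt_prep(d)
    rows <- seq_len(d$n_rows)
    pl <- lapply(prep$tg, mttree:::.mt_node_loss_prep, rows = rows)
    fast <- mttree:::.mt_best_split(prep, rows, hp, character(), pl)
    if (is.null(surface)) {
      expect_null(fast)
    } else {
      expect_equal(fast$feature, surface$feature)
      expect_equal(fast$kind, surface$kind)
      if (surface$kind == "numeric_threshold")
        expect_equal(fast$threshold, surface$threshold)
      else expect_equal(fast$level, surface$level)
      expect_equal(sort(fast$left), sort(surface$left_rows))
    }
  }
})

test_that("single-target avgIG/maxIG reduce to exhaustive CART search", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(15:30, 1)
    df <- data.frame(x1 = round(stats::runif(n), 2),
                     x2 = round(stats::runif(n), 2),
                     y = stats::rnorm(n))
    d <- one_target_data(df)
    for (method in c("avgIG", "maxIG")) {
      hp <- mt_control(evalmethod = method, splitmin = 3, cp = 0)
      win <- select_split(enumerate_candidates(d, hp), d, hp)
      # oracle: best variance-reduction split by explicit enumeration
      best <- NULL
      for (fn in c("x1", "x2")) {
        sv <- sort(unique(df[[fn]]))
        for (g in seq_len(length(sv) - 1)) {
          thr <- (sv[g] + sv[g + 1]) / 2
          l <- df$y[df[[fn]] <= thr]; r <- df$y[df[[fn]] > thr]
          if (length(l) < 3 || length(r) < 3) next
          ig <- oracle_sse(df$y) - oracle_sse(l) - oracle_sse(r)
          if (is.null(best) || ig > best$ig + 1e-12)
            best <- list(ig = ig, fn = fn, thr = thr)
        }
      }
      expect_equal(win$feature, best$fn)
      expect_equal(win$threshold, best$thr)
    }
  }
})

test_that("lookahead error is the normalised remaining loss", {
  df <- data.frame(x = c(1, 1, 2, 2), y = c(0, 0, 4, 4),
                   z = c(10, 12, 10, 12))
  ts <- mt_targets(mt_target("y", "continuous"),
                   mt_target("z", "continuous", weight = 3))
  d <- mt_dataset(df, ts)
  root <- mt_node_losses(d)
  left <- mt_node_losses(mt_subset(d, 1:2))
  right <- mt_node_losses(mt_subset(d, 3:4))
  err <- lookahead_error(list(left, right), root, ts)
  # by hand: y fully explained (0), z unchanged (8/8 = 1)
  expect_equal(err, (1 * 0 + 3 * 1) / 4)
  # all-pure leaves => 0; unsplit node => 1
  expect_equal(lookahead_error(list(root), root, ts), 1)
  pure <- lapply(root, function(l) { l$value <- 0; l })
  expect_equal(lookahead_error(list(pure, pure), root, ts), 0)
})

test_that("splitError with exhaustive parallelsplit matches the brute force", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(20:30, 1)
    d <- random_mtdata(n, n_num = 3, n_cat = 0,
                       types = c("continuous", "count"))
    hp <- mt_control(evalmethod = "splitError", splitmin = 4, nodesize = 8,
                     cp = 0, parallelsplit = 1000L, paralleldepth = 1L)
    cands <- enumerate_candidates(d, hp)
    win <- select_split(cands, d, hp)
    # oracle: grow the depth-1 subtree under EVERY candidate, minimise error
    root <- mt_node_losses(d)
    errs <- vapply(cands, function(cand) {
      lookahead_error(list(mt_node_losses(mt_subset(d, cand$left_rows)),
                           mt_node_losses(mt_subset(d, cand$right_rows))),
                      root, d$targets)
    }, 0)
    expect_equal(win$lookahead_error, min(errs), tolerance = 1e-12)
    best <- which(errs <= min(errs) + 1e-12)
    expect_true(any(vapply(best, function(i)
      identical(cands[[i]]$feature, win$feature) &&
        identical(cands[[i]]$threshold, win$threshold), TRUE)))
  }
})

test_that("selection is deterministic across repeated runs", {
  set.seed(77)
  d <- random_mtdata(40)
  hp <- mt_control(splitmin = 4)
  w1 <- select_split(enumerate_candidates(d, hp), d, hp)
  w2 <- select_split(enumerate_candidates(d, hp), d, hp)
  expect_identical(w1, w2)
})
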