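# Growth, prediction, evaluation, serialization.

sim_data <- function(n = 300, noise = 2, seed = 1) {
  sim <- mt_simulate(mt_plant_spec(n_rows = n, n_noise_features = noise,
                                   seed = seed))
  list(d = mt_dataset(sim$data, mt_sim_targets()), sim = sim)
}

test_that("depth and nodesize gates yield single-leaf trees", {
  s <- sim_data(60)
  m0 <- mt_grow(s$d, control = mt_control(d = 0))
  expect_equal(length(m0$nodes), 1L)
  expect_true(m0$nodes[[1]]$is_leaf)
  expect_equal(m0$nodes[[1]]$summary[[1]]$mean, mean(s$sim$data$y_cont))

  s10 <- sim_data(10)
  m <- mt_grow(s10$d, control = mt_control(nodesize = 20))
  expect_equal(mt_n_leaves(m), 1L)
})

test_that("growth requires a weighted target", {
  s <- sim_data(50)
  expect_error(mt_grow(s$d, mt_sim_targets(weights = c(0, 0, 0, 0))),
               class = "mt_config_error")
})

test_that("planted two-subgroup structure is recovered at the root", {
  sim <- mt_simulate(mt_plant_spec(seed = 1))  # generator defaults
  d <- mt_dataset(sim$data, mt_sim_targets())
  fit <- mt_grow(d, control = mt_control(d = 1))
  sp <- fit$nodes[[1]]$split
  expect_equal(sp$feature, "x1")
  x <- sim$data$x1
  gap <- c(max(x[x <= 0.5]), min(x[x > 0.5]))
  expect_gt(sp$threshold, gap[1])
  expect_lt(sp$threshold, gap[2])
})

test_that("routing training data reproduces training leaf assignment", {
  s <- sim_data(250, seed = 3)
  fit <- mt_grow(s$d, control = mt_control(d = 3, nodesize = 25))
  p <- predict(fit, s$sim$data)
  expect_equal(p$.leaf, fit$train_leaf)
  # single-leaf model: every row gets root summaries
  m0 <- mt_grow(s$d, control = mt_control(d = 0))
  p0 <- predict(m0, s$sim$data)
  expect_true(all(p0$y_cont == m0$nodes[[1]]$summary[[1]]$mean))
  expect_true(all(p0$.leaf == 1L))
})

test_that("hand-written model documents load and route as traced by hand", {
  doc <- '{
    "schema": "mttree/1",
    "control": {"evalmethod":"avgIG","d":2,"nodesize":4,"splitmin":2,
                "cp":0.01,"reuse":true,"alpha":0.05,"IGcutoff":0.1,
                "parallelsplit":5,"paralleldepth":2,"seed":1},
    "targets": [{"name":"y","type":"continuous","weight":1,
                 "event":null,"exposure":null}],
    "feature_info": {"names":["age","sex"],
                     "types":["numeric","categorical"],
                     "levels":{"sex":["F","M"]}},
    "surv_scales": {},
    "train_n": 8,
    "nodes": [
      {"id":1,"depth":0,"n":8,"is_leaf":false,
       "split":{"feature":"age","kind":"numeric_threshold","threshold":50,
                "level":null,"missing_side":"left"},
       "children":[2,3],
       "loss":[{"value":10,"n":8}],
       "summary":[{"mean":5,"n":8}]},
      {"id":2,"depth":1,"n":4,"is_leaf":false,
       "split":{"feature":"sex","kind":"level_vs_rest","threshold":null,
                "level":"F","missing_side":"right"},
       "children":[4,5],
       "loss":[{"value":4,"n":4}],
       "summary":[{"mean":2,"n":4}]},
      {"id":3,"depth":1,"n":4,"is_leaf":true,"split":null,"children":null,
       "loss":[{"value":4,"n":4}],"summary":[{"mean":8,"n":4}]},
      {"id":4,"depth":2,"n":2,"is_leaf":true,"split":null,"children":null,
       "loss":[{"value":1,"n":2}],"summary":[{"mean":1,"n":2}]},
      {"id":5,"depth":2,"n":2,"is_leaf":true,"split":null,"children":null,
       "loss":[{"value":1,"n":2}],"summary":[{"mean":3,"n":2}]}
    ]
  }'
  m <- mt_deserialize(doc)
  newdata <- data.frame(
    age = c(30, 30, 70, NA, 55),
    sex = c("F", "M", "F", "M", "X"))
  p <- predict(m, newdata)
  # traced: 30/F -> leaf4 (1); 30/M -> leaf5 (3); 70 -> leaf3 (8);
  # NA age -> missing_side left -> sex M -> leaf5 (3); 55 -> leaf3 (8)
  expect_equal(p$y, c(1, 3, 8, 3, 8))
  expect_equal(p$.leaf, c(4L, 5L, 3L, 5L, 3L))
})

test_that("unseen categorical levels route to the rest side with a note", {
  df <- data.frame(g = rep(c("a", "b"), each = 10),
                   y = rep(c(0, 10), each = 10))
  d <- mt_dataset(df, mt_targets(mt_target("y", "continuous")))
  fit <- mt_grow(d, control = mt_control(d = 1, nodesize = 4, splitmin = 2))
  expect_false(fit$nodes[[1]]$is_leaf)
  expect_message(p <- predict(fit, data.frame(g = c("a", "zzz"))),
                 "unseen")
  expect_equal(p$y[2], 10)  # "rest" side
  # schema error for a missing feature column
  expect_error(predict(fit, data.frame(h = 1)), class = "mt_config_error")
})

test_that("serialize/deserialize round-trips predictions bit-exactly", {
  s <- sim_data(150, seed = 5)
  fit <- mt_grow(s$d, control = mt_control(d = 3, nodesize = 15))
  m2 <- mt_deserialize(mt_serialize(fit))
  expect_identical(predict(m2, s$sim$data), predict(fit, s$sim$data))
  # file round trip
  path <- withr::local_tempfile(fileext = ".json")
  mt_save(fit, path)
  m3 <- mt_load(path)
  expect_identical(predict(m3, s$sim$data), predict(fit, s$sim$data))
  # truncated document -> parse error, not a partial model
  txt <- mt_serialize(fit)
  expect_error(mt_deserialize(substr(txt, 1, nchar(txt) - 50)),
               class = "mt_parse_error")
  # version mismatch -> explicit unsupported-version error
  bad <- sub("mttree/1", "mttree/999", txt, fixed = TRUE)
  expect_error(mt_deserialize(bad), class = "mt_config_error")
})

test_that("evaluation is 1 for a stump, 0 for a tree pure on test data", {
  # two perfectly separable groups, all four target types exactly constant
  # within group (all survival rows are events at a shared group time)
  df <- data.frame(x = rep(c(0, 1), each = 10),
                   y = rep(c(0, 4), each = 10),
                   lab = rep(c("L", "R"), each = 10),
                   cnt = rep(c(1, 3), each = 10),
                   tt = rep(c(1, 2), each = 10),
                   ev = 1)
  ts <- mt_targets(mt_target("y", "continuous"),
                   mt_target("lab", "categorical"),
                   mt_target("cnt", "count"),
                   mt_target("tt", "survival", event = "ev"))
  d <- mt_dataset(df, ts)
  fit <- mt_grow(d, control = mt_control(d = 2, nodesize = 4, splitmin = 2))
  ev <- mt_evaluate(fit, d)
  expect_equal(ev$overall, 0, tolerance = 1e-9)
  stump <- mt_grow(d, control = mt_control(d = 0))
  ev0 <- mt_evaluate(stump, d)
  expect_equal(ev0$overall, 1, tolerance = 1e-12)
  expect_equal(ev0$n_leaves, 1L)
  # zero-variance continuous test target: R^2 undefined, loss still reported
  df2 <- df; df2$y <- 1
  ev2 <- mt_evaluate(fit, mt_dataset(df2, ts))
  expect_true(is.na(ev2$per_target$y$r_squared))
  expect_true(is.finite(ev2$per_target$y$loss))
})

test_that("train/test overall errors agree on split halves of planted data", {
  # simulation property: held-out overall close to training overall
  diffs <- vapply(1:20, function(seed) {
    sim <- mt_simulate(mt_plant_spec(n_rows = 400, n_noise_features = 3,
                                     seed = seed))
    d <- mt_dataset(sim$data, mt_sim_targets())
    tr <- mt_subset(d, 1:200); te <- mt_subset(d, 201:400)
    fit <- mt_grow(tr, control = mt_control(d = 2))
    abs(mt_evaluate(fit, te)$overall - mt_evaluate(fit, tr)$overall)
  }, 0)
  expect_true(all(diffs < 0.15))
})

test_that("training overall error is non-increasing in depth", {
  s <- sim_data(300, noise = 3, seed = 9)
  errs <- vapply(0:4, function(dd) {
    fit <- mt_grow(s$d, control = mt_control(d = dd, nodesize = 20))
    mt_evaluate(fit, s$d)$overall
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("grown trees satisfy every structural constraint", {
  set.seed(15)
  for (rep in 1:5) {
    d <- random_mtdata(80, na_frac = 0.05)
    hp <- mt_control(d = 3, nodesize = sample(10:25, 1),
                     splitmin = sample(3:8, 1),
                     reuse = rep %% 2 == 0)
    fit <- mt_grow(d, control = hp)
    check_node <- function(id, used) {
      nd <- fit$nodes[[id]]
      expect_lte(nd$depth, hp$d)
      if (nd$is_leaf) {
        expect_gte(nd$n, min(hp$splitmin, fit$train_n))
      } else {
        expect_gte(nd$n, hp$nodesize)
        if (!hp$reuse) expect_false(nd$split$feature %in% used)
        used2 <- c(used, nd$split$feature)
        expect_equal(sum(vapply(nd$children,
                                function(c) fit$nodes[[c]]$n, 0)), nd$n)
        for (ch in nd$children) check_node(ch, used2)
      }
    }
    check_node(1L, character())
  }
})
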