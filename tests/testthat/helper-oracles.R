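# Independent oracles: brute-force / closed-form / stats-built-in
# implementations used to pin the package's computations. These must stay
# naive (explicit loops, numeric optimisation) and never call into the
# engine they check.

oracle_sse <- function(y) {
  m <- sum(y) / length(y)
  tot <- 0
  for (v in y) tot <- tot + (v - m)^2
  tot
}

oracle_gini_loss <- function(labels) {
  n <- length(labels)
  imp <- 1
  for (lv in unique(labels)) imp <- imp - (sum(labels == lv) / n)^2
  n * imp
}

# -2 max_lambda sum(y log(lambda E) - lambda E) by numeric optimisation.
oracle_count_loss <- function(y, e = rep(1, length(y))) {
  if (sum(y) == 0) return(0)
  ll <- function(lam) sum(ifelse(y > 0, y * log(lam * e), 0) - lam * e)
  opt <- stats::optimize(ll, c(1e-8, 1e4), maximum = TRUE, tol = 1e-12)
  -2 * opt$objective
}

# -2 max_lambda (D log lambda - lambda T) by numeric optimisation.
oracle_surv_loss <- function(times, events) {
  D <- sum(events)
  if (D == 0) return(0)
  ll <- function(lam) D * log(lam) - lam * sum(times)
  opt <- stats::optimize(ll, c(1e-8, 1e4), maximum = TRUE, tol = 1e-12)
  -2 * opt$objective
}

# Poisson GLM likelihood-ratio oracle for a binary split of a count target.
oracle_count_split_lr <- function(y, side, e = rep(1, length(y))) {
  f0 <- stats::glm(y ~ 1, family = stats::poisson(), offset = log(e))
  f1 <- stats::glm(y ~ side, family = stats::poisson(), offset = log(e))
  lr <- f0$deviance - f1$deviance
  list(lr = lr, p = stats::pchisq(lr, 1, lower.tail = FALSE))
}

# Exhaustive single-target CART reference (continuous target, numeric
# features, avgIG semantics): all midpoint thresholds, variance reduction,
# same constraints and tie-breaks as documented. Returns nested lists.
oracle_cart <- function(df, yname, fnames, d, nodesize, splitmin, cp,
                        depth = 0L) {
  y <- df[[yname]]
  n <- nrow(df)
  leaf <- list(leaf = TRUE, n = n, mean = mean(y))
  if (depth >= d || n < nodesize) return(leaf)
  parent <- oracle_sse(y)
  best <- NULL
  for (fi in seq_along(fnames)) {
    x <- df[[fnames[fi]]]
    sv <- sort(unique(x))
    if (length(sv) < 2) next
    for (gi in seq_len(length(sv) - 1)) {
      thr <- (sv[gi] + sv[gi + 1]) / 2
      lsel <- x <= thr
      if (sum(lsel) < splitmin || sum(!lsel) < splitmin) next
      ig <- parent - oracle_sse(y[lsel]) - oracle_sse(y[!lsel])
      prop <- if (parent <= 0) 0 else min(max(ig / parent, 0), 1)
      if (prop < cp) next
      key <- c(prop, -fi, -thr)
      if (is.null(best) ||
          prop > best$prop + 1e-15 ||
          (abs(prop - best$prop) <= 1e-15 &&
           (fi < best$fi || (fi == best$fi && thr < best$thr)))) {
        best <- list(prop = prop, fi = fi, thr = thr, lsel = lsel)
      }
    }
  }
  if (is.null(best)) return(leaf)
  list(leaf = FALSE, n = n, feature = fnames[best$fi], threshold = best$thr,
       left = oracle_cart(df[best$lsel, , drop = FALSE], yname, fnames, d,
                          nodesize, splitmin, cp, depth + 1L),
       right = oracle_cart(df[!best$lsel, , drop = FALSE], yname, fnames, d,
                           nodesize, splitmin, cp, depth + 1L))
}

# Flatten an mttree model into the oracle's nested shape for comparison.
mttree_as_nested <- function(model, id = 1L) {
  nd <- model$nodes[[id]]
  if (nd$is_leaf) return(list(leaf = TRUE, n = nd$n))
  list(leaf = FALSE, n = nd$n, feature = nd$split$feature,
       threshold = nd$split$threshold,
       left = mttree_as_nested(model, nd$children[1]),
       right = mttree_as_nested(model, nd$children[2]))
}

same_tree <- function(a, b, tol = 1e-9) {
  if (a$leaf != b$leaf || a$n != b$n) return(FALSE)
  if (a$leaf) return(TRUE)
  if (a$feature != b$feature) return(FALSE)
  if (abs(a$threshold - b$threshold) > tol) return(FALSE)
  same_tree(a$left, b$left, tol) && same_tree(a$right, b$right, tol)
}

# Minimal independent DOT validator: tokenizes and checks
#   digraph <id> { <stmt>* }   with node stmts `id [attrs];` and edge
# stmts `id -> id [attrs];`, quoted strings with \" escapes.
dot_parse <- function(text) {
  s <- paste(text, collapse = "\n")
  i <- 1L; n <- nchar(s)
  peek <- function() if (i <= n) substr(s, i, i) else ""
  skip_ws <- function() while (i <= n && grepl("[[:space:]]", peek())) i <<- i + 1L
  read_token <- function() {
    skip_ws()
    ch <- peek()
    if (ch == "") return(NULL)
    if (ch == '"') {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(s, j, j)
        if (cj == "\\") j <- j + 2L
        else if (cj == '"') break
        else j <- j + 1L
      }
      if (j > n) stop("unterminated string")
      tok <- substr(s, i, j); i <<- j + 1L
      return(list(type = "string", value = tok))
    }
    if (grepl("[A-Za-z0-9_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", substr(s, j, j))) j <- j + 1L
      tok <- substr(s, i, j - 1L); i <<- j
      return(list(type = "id", value = tok))
    }
    if (substr(s, i, i + 1L) == "->") { i <<- i + 2L
      return(list(type = "arrow", value = "->")) }
    i <<- i + 1L
    list(type = "punct", value = ch)
  }
  expect_tok <- function(type, value = NULL) {
    tk <- read_token()
    if (is.null(tk) || tk$type != type ||
        (!is.null(value) && tk$value != value))
      stop(sprintf("expected %s %s", type, value %||% ""))
    tk
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  expect_tok("id", "digraph")
  expect_tok("id")
  expect_tok("punct", "{")
  nodes <- character(0); edges <- list()
  repeat {
    tk <- read_token()
    if (is.null(tk)) stop("missing closing brace")
    if (tk$type == "punct" && tk$value == "}") break
    if (tk$type != "id") stop("statement must start with an identifier")
    head_id <- tk$value
    tk <- read_token()
    if (!is.null(tk) && tk$type == "arrow") {
      to <- expect_tok("id")$value
      edges[[length(edges) + 1L]] <- c(head_id, to)
      tk <- read_token()
    } else {
      if (head_id != "node") nodes <- c(nodes, head_id)
    }
    # optional attribute block
    if (!is.null(tk) && tk$type == "punct" && tk$value == "[") {
      repeat {
        tk <- read_token()
        if (is.null(tk)) stop("unterminated attribute block")
        if (tk$type == "punct" && tk$value == "]") break
      }
      tk <- read_token()
    }
    if (is.null(tk) || tk$type != "punct" || tk$value != ";")
      stop("statement must end with ';'")
  }
  skip_ws()
  if (i <= n) stop("trailing content after closing brace")
  list(nodes = unique(nodes), edges = edges)
}

# Random mixed-type dataset for property tests.
random_mtdata <- function(n, n_num = 2L, n_cat = 1L,
                          types = c("continuous", "categorical",
                                    "count", "survival"),
                          na_frac = 0) {
  df <- data.frame(row.names = seq_len(n))
  for (i in seq_len(n_num)) {
    x <- round(stats::runif(n, 0, 10), 2)
    if (na_frac > 0) x[stats::runif(n) < na_frac] <- NA
    df[[paste0("x", i)]] <- x
  }
  for (i in seq_len(n_cat)) {
    x <- sample(LETTERS[1:3], n, replace = TRUE)
    if (na_frac > 0) x[stats::runif(n) < na_frac] <- NA
    df[[paste0("c", i)]] <- x
  }
  ts <- list()
  signal <- df$x1
  signal[is.na(signal)] <- 5
  for (ty in types) {
    if (ty == "continuous") {
      df$y_num <- stats::rnorm(n, ifelse(signal > 5, 2, 0))
      ts <- c(ts, list(mt_target("y_num", "continuous")))
    } else if (ty == "categorical") {
      df$y_lab <- ifelse(stats::runif(n) < ifelse(signal > 5, 0.7, 0.3),
                         "P", "Q")
      ts <- c(ts, list(mt_target("y_lab", "categorical")))
    } else if (ty == "count") {
      df$y_cnt <- stats::rpois(n, ifelse(signal > 5, 4, 1))
      ts <- c(ts, list(mt_target("y_cnt", "count")))
    } else {
      tt <- stats::rexp(n, ifelse(signal > 5, 2, 0.5))
      cc <- stats::rexp(n, 0.5)
      df$y_tt <- pmin(tt, cc)
      df$y_ev <- as.numeric(tt <= cc)
      ts <- c(ts, list(mt_target("y_tt", "survival", event = "y_ev")))
    }
  }
  mt_dataset(df, mt_targets(ts))
}
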