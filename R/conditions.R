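# Typed conditions so callers (and the CLI) can distinguish user/config
# problems (exit 2) from internal failures (exit 1).

mt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mt_error")))
}

mt_stop_config <- function(msg) mt_stop(msg, "mt_config_error")
mt_stop_parse  <- function(msg) mt_stop(msg, "mt_parse_error")
mt_stop_domain <- function(msg) mt_stop(msg, "mt_domain_error")
mt_stop_internal <- function(msg) mt_stop(msg, "mt_internal_error")

# Run `expr` with a private RNG stream so library calls never disturb the
# caller's .Random.seed (and are reproducible given `seed`).
with_mt_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
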