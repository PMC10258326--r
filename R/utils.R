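# Time-unit conventions used throughout: survival times are stored in months,
# cycle lengths in days, discounting in years.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

months_to_years <- function(m) m * DAYS_PER_MONTH / DAYS_PER_YEAR
days_to_months <- function(d) d / DAYS_PER_MONTH
days_to_years <- function(d) d / DAYS_PER_YEAR

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the prior RNG
#' state afterwards so callers' random streams are untouched.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a deterministic 31-bit child seed from a parent seed and a stage label,
# so stages can be re-run in isolation with reproducible streams.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Nested-list access by dotted path, e.g. "prices.toripalimab_per_cycle".
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("unknown config parameter: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config_get(config, path) # errors if absent
  expr <- Reduce(function(x, k) call("[[", x, k), keys, init = quote(config))
  eval(call("<-", expr, value))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
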