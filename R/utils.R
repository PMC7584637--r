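# Internal helpers: classed conditions and scoped RNG.

bgcsel_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("bgcsel_", class), "bgcsel_error")))
}

bgcsel_warn <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "bgcsel_warning"))
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# All generators in the package are pure functions of (config, seed) via
# R's Mersenne-Twister; seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    bgcsel_stop("validation", "seed must be a single integer or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
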