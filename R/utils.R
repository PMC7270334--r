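# Shared small helpers: unit conversions, seeded evaluation, validation.

HOURS_PER_DAY <- 24

days_to_hours <- function(d) d * HOURS_PER_DAY
hours_to_days <- function(h) h / HOURS_PER_DAY

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards, so seeded internals do not
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# scalar positive check used by the constructors
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("'%s' must be a single positive finite number (got %s)",
                 name, paste(format(x), collapse = ", "))
  invisible(x)
}
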