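# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors (bad inputs, schema violations) vs inconsistency errors
# (mutually contradictory segregation calls).

hf_stop <- function(msg, class = "hifflux_validation_error", data = list()) {
  cond <- structure(
    class = c(class, "hifflux_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

hf_assert <- function(ok, msg, class = "hifflux_validation_error") {
  if (!isTRUE(ok)) hf_stop(msg, class = class)
  invisible(TRUE)
}

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulators do not
#' perturb the global random stream. With `seed = NULL` the expression runs
#' on the current stream.
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  hf_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
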