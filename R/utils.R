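## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are deterministic
#' without disturbing the session.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Classed error constructor: all package errors inherit "ehtkit_error" plus a
## specific subclass so tests can assert on failure modes.
eht_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "ehtkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

eht_warn <- function(subclass, msg) {
  warning(structure(
    class = c(subclass, "ehtkit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    eht_stop("eht_config_error",
             sprintf("`%s` must be a %s numeric scalar", name,
                     if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    eht_stop("eht_config_error", sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}
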