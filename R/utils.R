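# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing validation errors in the package carry the condition class
#' `"aerodose_error"` plus a specific subclass, so callers can distinguish
#' invalid inputs from degenerate fits programmatically.
#'
#' @noRd
abort <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "aerodose_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

abort_invalid <- function(message) abort(message, "aerodose_invalid_input")

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG to a deterministic state derived from `seed`, evaluates
#' `expr`, and restores the caller's `.Random.seed`, so simulation functions
#' are reproducible without clobbering the global stream.
#'
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Derive a stream-specific child seed from a base seed; kept below 2^31.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + 104729 * index) %% 2147483647
}
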