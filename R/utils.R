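#' Sentinel token used when a context window runs past a sentence edge
#'
#' Context windows shorter than `n` are filled with this sentinel; the
#' embedding layer maps it to the all-zero vector, signalling "no
#' information" to the model.
#'
#' @format A length-one character vector.
#' @export
PAD_TOKEN <- "<PAD>"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never clobbers user-level reproducibility.
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
    set.seed(seed)
  }
  force(expr)
}

stop_fl <- function(..., class) {
  stop(structure(
    class = c(class, "flavorlex_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_fl(name, " must be a single finite number in ",
            if (open_lower) "(" else "[", lower, ", ", upper,
            if (open_upper) ")" else "]",
            class = "flavorlex_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= lower && x == trunc(x)
  if (!ok) {
    stop_fl(name, " must be a single integer >= ", lower,
            class = "flavorlex_validation_error")
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
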