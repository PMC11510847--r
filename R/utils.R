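#' @importFrom rlang abort warn inform
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats approx rnorm runif rbinom rnbinom rexp setNames
NULL

# consistent error signalling: all user-facing argument errors share class
# "sevensload_error" plus a specific subclass usable in tests
stop_invalid <- function(msg, class = "invalid_argument") {
  abort(msg, class = c(class, "sevensload_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    stop_invalid(sprintf("`%s` = %g is outside the allowed range", name, x))
  }
  invisible(x)
}

# local seeding: set the RNG deterministically for one computation without
# clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a stream of child seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
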