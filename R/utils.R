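# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so library code never clobbers the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation; result always in [1, 2^31 - 2] so it is
# a valid 32-bit R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

stop_named <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rumenpls_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_matrix_like <- function(x, what = "x") {
  if (!is.matrix(x)) {
    if (is.data.frame(x)) x <- as.matrix(x)
    else stop_named("rumenpls_input_error", "%s must be a matrix", what)
  }
  if (!is.numeric(x)) stop_named("rumenpls_input_error", "%s must be numeric", what)
  x
}
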