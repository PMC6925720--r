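#' @importFrom rlang abort warn %||% .data :=
#' @importFrom stats plogis qlogis rbinom rnorm runif rpois rlogis qnorm
#'   pchisq pnorm glm binomial coef vcov optim setNames var sd cor
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Half-up rounding to `digits` decimals (round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_not_df <- function(data, arg = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", arg))
}
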