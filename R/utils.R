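# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed, keeping each within
# 32-bit integer range.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up in absolute value (so 0.005
#' rounds to 0.01), the convention used for printed report tables. Base R's
#' `round()` rounds half to even, which differs on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # 1e-9 absorbs binary representation error on exact decimal ties
  # (2.675 * 100 is stored just below 267.5)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
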