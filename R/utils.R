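# Internal helpers shared across modules.

# Round half away from zero (arithmetic rounding). base::round() rounds
# half to even, which does not reproduce published score tables; the eps
# guard absorbs binary representation error in 2-dp decimals (0.005 is
# not exactly representable).
round_half_up <- function(x, digits = 2) {
  stopifnot(digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

is_binary <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
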