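# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals: ties (x.x5) move away
#' from zero rather than to the even digit. Used wherever percentages and
#' ratios are reported at one decimal, so that e.g. 44.45 prints as 44.5.
#' A 1e-9 guard absorbs binary representation error in quotients that are
#' exact in decimal (889/20 = 44.45 is stored fractionally below 44.45).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
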