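# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for printed percentages and for integer-percent regrade
#' binning (base `round()` rounds half to even). A tiny epsilon absorbs
#' floating-point representation error so that values such as 80.5 obtained
#' from binary fractions land on the intended side of the tie.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))     # 1  2 -1
#' round_half_away(96.666667, 1)          # 96.7
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Evaluate `code` with a private RNG stream: seeds the global RNG, restores
# the previous state on exit so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

assert_probability <- function(p, what = deparse(substitute(p))) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

assert_grade <- function(g, what = deparse(substitute(g))) {
  if (!is.numeric(g) || anyNA(g) || any(g != as.integer(g)) ||
      any(g < 1L) || any(g > 5L)) {
    stop(sprintf("`%s` must be an integer grade in 1..5", what), call. = FALSE)
  }
  invisible(as.integer(g))
}
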