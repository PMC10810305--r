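#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov approx pf pt qt quantile rnorm sd splinefun TukeyHSD
#'   setNames runif
#' @importFrom utils read.csv
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Trapezoid rule with uniform spacing `dx`.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

rms <- function(x) sqrt(mean(x^2))
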