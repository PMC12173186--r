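#' Round half away from zero
#'
#' Printed tables in this field round half-up, unlike [round()]'s
#' round-half-even. Comparisons against printed values therefore use this
#' helper.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  z <- abs(x) * 10^digits
  # guard against representation error just below .5 (e.g. 0.1715*1000)
  sign(x) * trunc(z + 0.5 + sqrt(.Machine$double.eps)) / 10^digits
}

# evaluate expr with a local RNG seeded at `seed`, restoring global state
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

region_categories <- c("eastern", "central", "western")

stop_regcap <- function(...) stop(..., call. = FALSE)
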