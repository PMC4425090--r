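#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed process tables use
#' conventional half-up rounding (52.25 -> 52.3 at one decimal, -104.25 ->
#' -104.3). Used wherever a value is rendered at a table's printed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_up(104.25, 1)  # 104.3, where round() gives 104.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_domain(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

#' Run an expression with a private RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (spec, seed) without clobbering the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
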