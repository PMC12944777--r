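#' Round half away from zero
#'
#' Fixed-precision rounding where ties go away from zero (so 0.125 -> 0.13
#' and -0.125 -> -0.13 at 2 digits), the convention used by SAS-era clinical
#' tables. Base R's `round()` rounds ties to even, which disagrees with
#' printed screening tables on exactly those boundary values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125, 0.0365), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Proportion -> printed percentage (2 decimals, half away from zero).
as_pct <- function(x, digits = 2) round_half_up(100 * x, digits)

stop_config <- function(msg, ...) {
  abort(msg, class = "ruleout_config_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "ruleout_validation_error", ...)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "ruleout_input_error", ...)
}

# Evaluate an expression with a private RNG stream: the global .Random.seed
# is untouched, and `seed = NULL` means "use the current stream".
with_private_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1 || is.na(seed))) {
    stop_config("`seed` must be a single integer or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  expr
}
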