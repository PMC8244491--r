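## Shared helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Report-style rounding used throughout the package (R's `round()` is
#' round-half-even, which disagrees with how thermodynamic tables are
#' conventionally printed).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
#' @noRd
AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2("'%s' must be a single finite number", name)
  invisible(x)
}
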