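#' Round half away from zero
#'
#' Printed energies and potency ratios follow the usual bench convention of
#' rounding halves away from zero, which differs from [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(0.25, 1)   # 0.3
#' round_half_away(-3.545, 2) # -3.55 (within floating tolerance)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signif() to 3 figures used for reported K_D values
signif3 <- function(x) signif(x, 3)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

abr_file <- function(...) {
  f <- system.file("extdata", ..., package = "abrefine", mustWork = FALSE)
  if (!nzchar(f)) stopf("bundled resource not found: %s", file.path(...))
  f
}
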