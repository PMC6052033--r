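## Internal helpers shared across modules.

#' Logarithmically spaced time grid
#'
#' Builds the default output grid for rebinding simulations: points uniformly
#' spaced in log10(time) between `from` and `to` seconds.
#'
#' @param from,to Grid limits in seconds; both must be positive.
#' @param pointsPerDecade Number of points per decade (default 100).
#' @return Numeric vector of strictly increasing times in seconds.
#' @examples
#' t <- logTimeGrid(1e-13, 1, pointsPerDecade = 10)
#' range(t)
#' @export
logTimeGrid <- function(from = 1e-13, to = 1, pointsPerDecade = 100) {
  if (!is.numeric(from) || !is.numeric(to) || from <= 0 || to <= from)
    stop("'from' and 'to' must satisfy 0 < from < to", call. = FALSE)
  nDec <- log10(to) - log10(from)
  n <- max(2L, round(nDec * pointsPerDecade) + 1L)
  10^seq(log10(from), log10(to), length.out = n)
}

## log-time linear interpolation of a curve at time t
.interpLogTime <- function(times, values, t) {
  stats::approx(log10(times), values, xout = log10(t), rule = 1)$y
}

.assertFinite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'", name, "' must be finite numeric", call. = FALSE)
  invisible(x)
}

## round half away from zero at given decimals (base round() is half-to-even)
.roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## two-significant-figure style rounding used when echoing tabulated rates
.signifTable <- function(x, scale = 1e8, digits = 1) {
  .roundHalfAway(x / scale, digits)
}
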