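## Synthetic-data generators: scheme-generated progress curves with realistic
## noise, and rank-1 transient-absorption maps built from a parametric
## two-band difference spectrum. All randomness is seeded and reproducible.

#' NoiseModel: seeded noise specification
#'
#' @slot multSigma Multiplicative noise fraction (relative to the signal).
#' @slot addSigma Additive noise (absolute units; for maps interpreted as a
#'   fraction of the peak amplitude).
#' @slot seed Integer seed; the same seed yields identical output.
#' @export
setClass("NoiseModel",
  representation(multSigma = "numeric", addSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@multSigma < 0 || object@addSigma < 0)
      return("noise sigmas must be >= 0")
    TRUE
  }
)

#' Construct a NoiseModel
#'
#' @param multSigma Multiplicative sigma (default 0.01, typical
#'   flash-photolysis quality).
#' @param addSigma Additive sigma (default 0).
#' @param seed Integer seed (default 1).
#' @return A [NoiseModel-class] object.
#' @export
noiseModel <- function(multSigma = 0.01, addSigma = 0, seed = 1L) {
  methods::new("NoiseModel", multSigma = as.numeric(multSigma),
               addSigma = as.numeric(addSigma), seed = as.integer(seed))
}

#' BandShape: one Gaussian band of a difference spectrum
#'
#' @slot center Band center (nm).
#' @slot width Gaussian standard deviation (nm, > 0).
#' @slot amplitude Signed amplitude (differential absorbance units).
#' @export
setClass("BandShape",
  representation(center = "numeric", width = "numeric",
                 amplitude = "numeric"),
  validity = function(object) {
    if (object@width <= 0) return("'width' must be > 0")
    TRUE
  }
)

#' Construct a BandShape
#'
#' @param center,width,amplitude Band center (nm), Gaussian width (nm) and
#'   signed amplitude.
#' @return A [BandShape-class] object.
#' @export
BandShape <- function(center, width, amplitude) {
  methods::new("BandShape", center = as.numeric(center),
               width = as.numeric(width), amplitude = as.numeric(amplitude))
}

#' Default two-band difference spectrum with prescribed zero crossings
#'
#' Builds the photoproduct-minus-complex Soret difference spectrum as a broad
#' positive deoxy band plus a sharp negative CO-complex bleach, solving for
#' the band widths and amplitude ratio that place the two zero crossings at
#' the requested wavelengths. With the defaults the crossings sit at 402 and
#' 426 nm, the isosbestic points of the NP7 CO photocycle.
#'
#' @param crossings Two zero-crossing wavelengths (nm).
#' @param centers Photoproduct and bleach band centers (nm).
#' @param bleachWidth Gaussian width of the bleach band (nm).
#' @param scale Peak bleach amplitude (differential absorbance units).
#' @return List of two [BandShape-class] objects (photoproduct, bleach).
#' @examples
#' b <- differenceBands()
#' vapply(b, function(x) x@center, numeric(1))
#' @export
differenceBands <- function(crossings = c(402, 426), centers = c(436, 416),
                            bleachWidth = 6.5, scale = 0.05) {
  x1 <- crossings[1]; x2 <- crossings[2]
  c1 <- centers[1]; c2 <- centers[2]
  num <- (x2 - c1)^2 - (x1 - c1)^2
  den <- (x2 - c2)^2 - (x1 - c2)^2
  if (den == 0 || num / den <= 0)
    stop("no Gaussian pair with these centers crosses zero at both ",
         "requested wavelengths", call. = FALSE)
  w2 <- bleachWidth
  w1 <- sqrt(num / den) * w2
  logRatio <- (x1 - c1)^2 / (2 * w1^2) - (x1 - c2)^2 / (2 * w2^2)
  a1 <- scale * exp(logRatio)
  list(BandShape(c1, w1, a1), BandShape(c2, w2, -scale))
}

## evaluate a sum of Gaussian bands on a wavelength grid
.bandSpectrum <- function(bands, wavelengths) {
  Reduce(`+`, lapply(bands, function(b)
    b@amplitude * exp(-(wavelengths - b@center)^2 / (2 * b@width^2))))
}

#' Generate a noisy rebinding progress curve
#'
#' Simulates the scheme and perturbs the result with the seeded noise model:
#' N' = N (1 + multSigma e1) + addSigma e2, clipped at zero. With zero sigmas
#' the simulation is returned unchanged. The per-point noise standard
#' deviation is stored in the curve's sigma field.
#'
#' @param rts A [MicroRates-class] object, or the name of a shipped rate set
#'   (see [np7Rates()], e.g. `"wt_pH5.5"`).
#' @param condition A [Condition-class].
#' @param times Output time grid (default [logTimeGrid()]).
#' @param noise A [NoiseModel-class] (default 1 percent multiplicative,
#'   seed 1).
#' @param topology A [SchemeTopology-class].
#' @return A [ProgressCurve-class] with sigma set when noise is non-zero.
#' @examples
#' crv <- genProgressCurve("wt_pH5.5", Condition(coAtm = 1),
#'                         times = logTimeGrid(1e-13, 1, 10))
#' @export
genProgressCurve <- function(rts, condition, times = logTimeGrid(),
                             noise = noiseModel(),
                             topology = defaultTopology()) {
  if (is.character(rts))
    rts <- readRateSet(system.file("extdata", "np7_rates.yaml",
                                   package = "nprebind"), rts)
  clean <- simulateRebinding(rts, topology, condition, times)
  if (noise@multSigma == 0 && noise@addSigma == 0) return(clean)
  N <- clean@fraction
  sigma <- sqrt((noise@multSigma * N)^2 + noise@addSigma^2)
  noisy <- withr::with_seed(noise@seed,
    N * (1 + noise@multSigma * stats::rnorm(length(N))) +
      noise@addSigma * stats::rnorm(length(N)))
  s3 <- 3 * max(sigma)
  ProgressCurve(times, pmin(pmax(noisy, 0), 1 + s3),
                pmax(sigma, 1e-6))
}

#' Generate a rank-1 transient-absorption map
#'
#' Builds D(lambda, t) = s(lambda) N(t) + additive noise, with s the two-band
#' difference spectrum. The generated map is exactly rank 1 before noise; its
#' zero crossings are time-invariant isosbestic points by construction.
#'
#' @param kinetics A [ProgressCurve-class] supplying N(t) on the delay axis.
#' @param bands List of [BandShape-class] objects (default
#'   [differenceBands()]).
#' @param wavelengths Wavelength grid in nm (must cover the bands).
#' @param noise A [NoiseModel-class]; `addSigma` is applied as a fraction of
#'   the peak |deltaA| (default 0.5 percent, reflecting the better-than-1e-4
#'   sensitivity of broadband detection on a few-mOD signal).
#' @return A [TAMap-class].
#' @examples
#' t <- logTimeGrid(1e-11, 2e-9, 5)
#' crv <- ProgressCurve(t, exp(-t / 1e-9))
#' map <- genTAMap(crv)
#' findIsosbestic(map)
#' @export
genTAMap <- function(kinetics, bands = differenceBands(),
                     wavelengths = seq(380, 470, by = 0.5),
                     noise = noiseModel(multSigma = 0, addSigma = 0.005)) {
  centers <- vapply(bands, function(b) b@center, numeric(1))
  if (min(centers) < min(wavelengths) || max(centers) > max(wavelengths))
    stop("'wavelengths' must cover both band centers", call. = FALSE)
  amps <- vapply(bands, function(b) b@amplitude, numeric(1))
  if (length(unique(sign(amps[amps != 0]))) < 2L)
    warning("bands have equal sign: the spectrum has no zero crossing",
            call. = FALSE)
  s <- .bandSpectrum(bands, wavelengths)
  D <- outer(s, kinetics@fraction)
  if (noise@addSigma > 0 || noise@multSigma > 0) {
    peak <- max(abs(D))
    D <- withr::with_seed(noise@seed,
      D * (1 + noise@multSigma * stats::rnorm(length(D))) +
        noise@addSigma * peak * stats::rnorm(length(D)))
  }
  TAMap(wavelengths, kinetics@times, D)
}
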