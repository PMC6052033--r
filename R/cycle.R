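## Proton-linkage thermodynamic cycle: aspartate ionization coupled to the
## closed <-> open conformational transition.
##
## Species (superscript 0 = protonated, - = ionized):
##   C0 (closed, protonated)   C- (closed, ionized)
##   O0 (open, protonated)     O- (open, ionized)
## Equilibria: Ka^C = [C-][H]/[C0], Ka^O = [O-][H]/[O0],
##             K_D = [O-]/[C-],     K_H = [O0]/[C0].
## Closure K_D/K_H = Ka^O/Ka^C is enforced by deriving K_H.

#' @rdname kH
setMethod("kH", "CycleParameters", function(object) {
  object@kD * 10^(object@pkaOpen - object@pkaClosed)
})

## log (natural) statistical weights of the four species relative to C0.
## Working in log space avoids overflow at extreme pH or K_D.
.logWeights <- function(cycle, pH) {
  ln10 <- log(10)
  lCm <- (pH - cycle@pkaClosed) * ln10            # C-/C0 = Ka^C/[H]
  cbind(C0 = 0,
        Cm = lCm,
        O0 = log(cycle@kD) + (cycle@pkaOpen - cycle@pkaClosed) * ln10, # K_H
        Om = lCm + log(cycle@kD))                 # O-/C- = K_D
}

#' Populations of the four proton-linkage species
#'
#' Computes the fractional populations of the closed-protonated (C0),
#' closed-ionized (C-), open-protonated (O0) and open-ionized (O-) species at
#' one or more pH values, taking the closed-protonated species as reference
#' and applying the three equilibrium relations before normalizing. Weights
#' are handled in log space, so extreme pH values do not overflow.
#'
#' @param cycle A [CycleParameters-class] object.
#' @param pH Numeric vector of pH values.
#' @return A data.frame with columns `pH`, `fC0`, `fCm`, `fO0`, `fOm`,
#'   `fClosed` (= fC0 + fCm) and `fOpen` (= fO0 + fOm); one row per pH.
#' @examples
#' np4 <- CycleParameters(4.3, 8.9, 100)
#' speciesFractions(np4, c(5.5, 7.5))
#' @export
speciesFractions <- function(cycle, pH) {
  methods::validObject(cycle)
  .assertFinite(pH, "pH")
  lw <- .logWeights(cycle, pH)
  w <- exp(lw - apply(lw, 1L, max))
  f <- w / rowSums(w)
  data.frame(pH = pH, fC0 = f[, "C0"], fCm = f[, "Cm"],
             fO0 = f[, "O0"], fOm = f[, "Om"],
             fClosed = f[, "C0"] + f[, "Cm"],
             fOpen = f[, "O0"] + f[, "Om"],
             row.names = NULL)
}

#' @rdname apparentPKa
#' @details The apparent pKa is the midpoint of the proton-linked transition:
#'   pKa(open) + pKa(closed) - log10((K_D + 1) / (K_D Ka^C + Ka^O)),
#'   with Ka^X = 10^-pKa(X). It equals the pH at which the titratable
#'   aspartate is half protonated in the four-state cycle, and runs
#'   monotonically from pKa(closed) (K_D -> 0) to pKa(open) (K_D -> Inf).
setMethod("apparentPKa", "CycleParameters", function(object) {
  kaO <- 10^(-object@pkaOpen)
  kaC <- 10^(-object@pkaClosed)
  object@pkaOpen + object@pkaClosed -
    log10((object@kD + 1) / (object@kD * kaC + kaO))
})

#' Midpoint pH of the proton-linked transition by root finding
#'
#' Independent numerical check of [apparentPKa()]: finds the pH at which the
#' protonated fraction of the titratable aspartate (fC0 + fO0) equals 1/2,
#' by bracketed root finding on [speciesFractions()]. Note that the
#' open-state population fO0 + fOm crosses 1/2 at a slightly different pH
#' (and never does when K_D < 1 or K_H > 1); the conformational transition is
#' driven by, and tracks, the protonation equilibrium, whose midpoint is what
#' the closed-form apparent pKa expresses.
#'
#' @param cycle A [CycleParameters-class] object.
#' @param interval pH search bracket (default c(-2, 16)).
#' @param tol Root tolerance in pH units (default 1e-6).
#' @return The midpoint pH.
#' @examples
#' transitionMidpointPH(CycleParameters(4.3, 8.9, 100))  # ~6.9
#' @export
transitionMidpointPH <- function(cycle, interval = c(-2, 16), tol = 1e-6) {
  methods::validObject(cycle)
  g <- function(pH) {
    f <- speciesFractions(cycle, pH)
    f$fC0 + f$fO0 - 0.5
  }
  lo <- g(interval[1]); hi <- g(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("no transition midpoint inside the pH bracket [",
         interval[1], ", ", interval[2], "]", call. = FALSE)
  stats::uniroot(g, interval = interval, tol = tol)$root
}

#' Ratio of the ionization constants in the open and closed states
#'
#' By cycle closure this equals the ratio of conformational constants:
#' Ka(open)/Ka(closed) = 10^(pkaClosed - pkaOpen) = K_D/K_H.
#'
#' @param pkaOpen,pkaClosed Microscopic pKa values.
#' @return Ka(open)/Ka(closed), dimensionless.
#' @examples
#' ionizationRatio(4.1, 6.9)   # ~631 for wt NP7
#' ionizationRatio(4.1, 5.7)   # ~40 for NP7(E27Q)
#' ionizationRatio(4.3, 8.5)   # ~16,000 for NP4
#' @export
ionizationRatio <- function(pkaOpen, pkaClosed) {
  .assertFinite(pkaOpen, "pkaOpen")
  .assertFinite(pkaClosed, "pkaClosed")
  10^(pkaClosed - pkaOpen)
}

#' Estimate K_D from an ionization-constant ratio
#'
#' Assuming the conformational equilibrium between the neutral (protonated)
#' species is shared with a reference protein, K_D = K_H(ref) x
#' Ka(open)/Ka(closed). The default reference is the NP4 cycle with K_D = 100
#' and the literature pKa pair 4.3/8.5, giving K_H(ref) = 100 * 10^(4.3-8.5).
#'
#' @param ratio Ionization-constant ratio Ka(open)/Ka(closed).
#' @param kHRef Reference conformational constant K_H for the protonated
#'   protein.
#' @return Estimated K_D.
#' @examples
#' estimateKd(ionizationRatio(4.1, 6.9))  # ~4 for wt NP7
#' @export
estimateKd <- function(ratio, kHRef = 100 * 10^(4.3 - 8.5)) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be finite and > 0", call. = FALSE)
  if (!is.numeric(kHRef) || !is.finite(kHRef) || kHRef <= 0)
    stop("'kHRef' must be finite and > 0", call. = FALSE)
  kHRef * ratio
}

#' Apparent pKa as a function of the conformational constant
#'
#' Evaluates the closed-form apparent pKa on a grid of K_D values for a fixed
#' microscopic pKa pair. The curve decreases monotonically from pKa(closed)
#' at small K_D to pKa(open) at large K_D.
#'
#' @param pkaOpen,pkaClosed Microscopic pKa values.
#' @param kdGrid Numeric vector of K_D values (> 0).
#' @return A data.frame with columns `kD` and `apparentPKa`.
#' @examples
#' apparentPKaCurve(4.3, 8.9, 10^seq(-2, 4, length.out = 7))
#' @export
apparentPKaCurve <- function(pkaOpen, pkaClosed, kdGrid) {
  if (length(kdGrid) == 0L)
    stop("'kdGrid' must be non-empty", call. = FALSE)
  if (any(!is.finite(kdGrid)) || any(kdGrid <= 0))
    stop("all K_D values must be finite and > 0", call. = FALSE)
  pka <- vapply(kdGrid, function(kd)
    apparentPKa(CycleParameters(pkaOpen, pkaClosed, kd)), numeric(1))
  data.frame(kD = kdGrid, apparentPKa = pka)
}

#' Round a fraction to a printed percentage
#'
#' Convenience used when echoing population tables: converts a fraction to a
#' percentage rounded half away from zero at the requested number of
#' decimals. Raw fractions elsewhere in the package are never rounded.
#'
#' @param f Fraction in [0, 1].
#' @param digits Decimal places of the percentage (default 1).
#' @return Percentage.
#' @export
asPercent <- function(f, digits = 1) .roundHalfAway(100 * f, digits)
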