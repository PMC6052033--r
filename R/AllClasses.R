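## S4 classes for the rebinding-kinetics toolkit.

#' CycleParameters: proton-linked conformational cycle
#'
#' Parameters of the four-state thermodynamic cycle coupling ionization of a
#' buried aspartate (Asp32 in NP7, Asp30 in NP4) to the closed-open
#' conformational transition of the nitrophorin AB/GH loops. The four species
#' are closed-protonated (C0), closed-ionized (C-), open-protonated (O0) and
#' open-ionized (O-).
#'
#' The conformational constant of the protonated protein, K_H, is not a free
#' slot: cycle closure K_D/K_H = Ka(open)/Ka(closed) is enforced by deriving it
#' with [kH()].
#'
#' @slot pkaOpen Microscopic pKa of the aspartate in the open state.
#' @slot pkaClosed Microscopic pKa in the closed state.
#' @slot kD Conformational equilibrium constant open/closed for the ionized
#'   protein (must be > 0).
#' @seealso [speciesFractions()], [apparentPKa()], [kH()]
#' @export
setClass("CycleParameters",
  representation(pkaOpen = "numeric", pkaClosed = "numeric", kD = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@pkaOpen) != 1L || !is.finite(object@pkaOpen))
      msg <- c(msg, "'pkaOpen' must be a single finite number")
    if (length(object@pkaClosed) != 1L || !is.finite(object@pkaClosed))
      msg <- c(msg, "'pkaClosed' must be a single finite number")
    if (length(object@kD) != 1L || !is.finite(object@kD) || object@kD <= 0)
      msg <- c(msg, "'kD' must be a single finite number > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CycleParameters object
#'
#' @param pkaOpen,pkaClosed Microscopic pKa values of the aspartate in the
#'   open and closed conformations.
#' @param kD Open/closed conformational equilibrium constant of the ionized
#'   protein.
#' @return A [CycleParameters-class] object.
#' @examples
#' np4 <- CycleParameters(pkaOpen = 4.3, pkaClosed = 8.9, kD = 100)
#' apparentPKa(np4)
#' @export
CycleParameters <- function(pkaOpen, pkaClosed, kD) {
  methods::new("CycleParameters", pkaOpen = as.numeric(pkaOpen),
               pkaClosed = as.numeric(pkaClosed), kD = as.numeric(kD))
}

## ---------------------------------------------------------------------------

.rateNames <- c("k_m1", "k_2", "k_m2", "k_3", "k_m3",
                "k_c", "k_mc", "k_d", "k_md", "k_e", "k_me")

#' MicroRates: microscopic rate constants of the rebinding scheme
#'
#' Holds the 11 microscopic rate constants of the minimal seven-state CO
#' rebinding scheme. All rates are first order (s^-1) except `k_m2`, the
#' bimolecular solvent re-entry constant (M^-1 s^-1) which is multiplied by
#' the CO concentration when the rate matrix is built.
#'
#' @slot rates Named numeric vector with elements
#'   `k_m1` (distal pocket -> bound rebinding), `k_2` (distal pocket ->
#'   solvent escape), `k_m2` (solvent -> distal pocket, M^-1 s^-1),
#'   `k_3`/`k_m3` (deoxy protein <-> relaxed slowly-reactive conformation),
#'   `k_c`/`k_mc` (distal pocket <-> back-tunnel site T2),
#'   `k_d`/`k_md` (T2 <-> back-tunnel site T3, or DP <-> T3 depending on
#'   topology), `k_e`/`k_me` (distal pocket <-> near-pocket site T4).
#' @export
setClass("MicroRates",
  representation(rates = "numeric"),
  validity = function(object) {
    r <- object@rates
    if (!identical(names(r), .rateNames))
      return(sprintf("rates must be named exactly: %s",
                     paste(.rateNames, collapse = ", ")))
    if (any(!is.finite(r)) || any(r < 0))
      return("all rates must be finite and >= 0")
    if (r[["k_m1"]] <= 0)
      return("'k_m1' (rebinding from the distal pocket) must be > 0")
    TRUE
  }
)

#' Construct a MicroRates object
#'
#' @param k_m1,k_2,k_m2,k_3,k_m3,k_c,k_mc,k_d,k_md,k_e,k_me Microscopic rate
#'   constants; see [MicroRates-class]. Unset side-cavity and relaxation rates
#'   default to 0 (edge absent).
#' @return A [MicroRates-class] object.
#' @examples
#' r <- MicroRates(k_m1 = 1e10, k_2 = 8e8, k_m2 = 1.6e8)
#' effectiveKon(r)
#' @export
MicroRates <- function(k_m1, k_2 = 0, k_m2 = 0, k_3 = 0, k_m3 = 0,
                       k_c = 0, k_mc = 0, k_d = 0, k_md = 0,
                       k_e = 0, k_me = 0) {
  r <- c(k_m1 = k_m1, k_2 = k_2, k_m2 = k_m2, k_3 = k_3, k_m3 = k_m3,
         k_c = k_c, k_mc = k_mc, k_d = k_d, k_md = k_md,
         k_e = k_e, k_me = k_me)
  methods::new("MicroRates", rates = stats::setNames(as.numeric(r), .rateNames))
}

## ---------------------------------------------------------------------------

.schemeStates <- c("BOUND", "DP", "T2", "T3", "T4", "SOLV", "RELAX")

#' SchemeTopology: wiring of the rebinding scheme
#'
#' The seven kinetic states are BOUND (heme-ligated), DP (photolyzed ligand in
#' the distal pocket), T2/T3 (back-tunnel docking sites), T4 (near-pocket
#' docking site), SOLV (ligand in solvent, deoxy protein) and RELAX (slowly
#' reactive relaxed conformation). Edges map rate labels of
#' [MicroRates-class] onto directed transitions; BOUND is absorbing and the
#' SOLV -> DP edge is the only concentration-scaled one.
#'
#' @slot states Character vector of state names.
#' @slot edges data.frame with columns `from`, `to`, `rate` (a MicroRates
#'   label).
#' @export
setClass("SchemeTopology",
  representation(states = "character", edges = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!setequal(object@states, .schemeStates))
      msg <- c(msg, "states must be the seven canonical scheme states")
    e <- object@edges
    if (!all(c("from", "to", "rate") %in% names(e)))
      msg <- c(msg, "edges needs columns from, to, rate")
    else {
      if (!all(e$from %in% object@states) || !all(e$to %in% object@states))
        msg <- c(msg, "edge endpoints must be scheme states")
      if (!all(e$rate %in% .rateNames))
        msg <- c(msg, "every edge rate label must map to a MicroRates field")
      if (any(duplicated(e$rate)))
        msg <- c(msg, "each rate label may drive exactly one edge")
      if (any(e$from == "BOUND"))
        msg <- c(msg, "BOUND must be absorbing (no outgoing edges)")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Default topology of the rebinding scheme
#'
#' After photolysis the ligand starts in DP, from which it can rebind
#' (`k_m1`), escape to solvent (`k_2`, re-entry `k_m2`[CO]), or migrate to the
#' docking sites. The published wiring of the back tunnel is ambiguous between
#' a linear chain DP-T2-T3 and a star DP-T3, so both are available.
#'
#' @param backTunnel `"T2-T3"` (default; linear chain DP<->T2<->T3 with
#'   `k_d`/`k_md` on the T2<->T3 leg) or `"DP-T3"` (T3 wired directly to DP).
#' @return A [SchemeTopology-class] object.
#' @export
defaultTopology <- function(backTunnel = c("T2-T3", "DP-T3")) {
  backTunnel <- match.arg(backTunnel)
  t3from <- if (backTunnel == "T2-T3") "T2" else "DP"
  edges <- rbind(
    data.frame(from = "DP",    to = "BOUND", rate = "k_m1"),
    data.frame(from = "DP",    to = "SOLV",  rate = "k_2"),
    data.frame(from = "SOLV",  to = "DP",    rate = "k_m2"),
    data.frame(from = "SOLV",  to = "RELAX", rate = "k_3"),
    data.frame(from = "RELAX", to = "SOLV",  rate = "k_m3"),
    data.frame(from = "DP",    to = "T2",    rate = "k_c"),
    data.frame(from = "T2",    to = "DP",    rate = "k_mc"),
    data.frame(from = t3from,  to = "T3",    rate = "k_d"),
    data.frame(from = "T3",    to = t3from,  rate = "k_md"),
    data.frame(from = "DP",    to = "T4",    rate = "k_e"),
    data.frame(from = "T4",    to = "DP",    rate = "k_me")
  )
  methods::new("SchemeTopology", states = .schemeStates, edges = edges)
}

## ---------------------------------------------------------------------------

#' Condition: experimental condition of a rebinding measurement
#'
#' @slot coConcentration CO concentration in M (pseudo-first-order; assumed
#'   constant during rebinding).
#' @slot photolyzedFraction Fraction of molecules photolyzed (metadata; curves
#'   are normalized per photolyzed molecule).
#' @slot temperature Temperature in degrees Celsius (metadata).
#' @export
setClass("Condition",
  representation(coConcentration = "numeric", photolyzedFraction = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@coConcentration) != 1L ||
        !is.finite(object@coConcentration) || object@coConcentration <= 0)
      msg <- c(msg, "'coConcentration' must be a single number > 0")
    if (object@photolyzedFraction <= 0 || object@photolyzedFraction > 1)
      msg <- c(msg, "'photolyzedFraction' must be in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Condition
#'
#' @param coConcentration CO concentration (M). Alternatively give `coAtm`.
#' @param coAtm CO partial pressure in atm, converted with Henry's law at
#'   20 C (`henry` M/atm).
#' @param photolyzedFraction Fraction photolyzed (default 1).
#' @param temperature Temperature, degrees C (default 20).
#' @param henry Henry's-law solubility used for the atm -> M conversion
#'   (default 1.0e-3 M/atm for CO in water at 20 C).
#' @return A [Condition-class] object.
#' @examples
#' Condition(coAtm = 1)     # 1 atm CO -> 1e-3 M
#' Condition(coAtm = 0.1)   # 0.1 atm CO -> 1e-4 M
#' @export
Condition <- function(coConcentration = NULL, coAtm = NULL,
                      photolyzedFraction = 1, temperature = 20,
                      henry = 1.0e-3) {
  if (is.null(coConcentration)) {
    if (is.null(coAtm))
      stop("give either 'coConcentration' (M) or 'coAtm' (atm)", call. = FALSE)
    coConcentration <- coAtm * henry
  }
  methods::new("Condition", coConcentration = as.numeric(coConcentration),
               photolyzedFraction = as.numeric(photolyzedFraction),
               temperature = as.numeric(temperature))
}

## ---------------------------------------------------------------------------

#' ProgressCurve: fraction of unliganded molecules versus time
#'
#' Rebinding progress curve N(t): the fraction of photolyzed molecules not yet
#' rebound, on a (by default log-spaced) strictly increasing time grid.
#'
#' @slot times Times in seconds, strictly increasing.
#' @slot fraction N(t) in [0, 1] (noisy curves may exceed 1 by up to three
#'   noise standard deviations).
#' @slot sigma Optional per-point noise standard deviation (length 0 when
#'   absent).
#' @export
setClass("ProgressCurve",
  representation(times = "numeric", fraction = "numeric", sigma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@fraction))
      msg <- c(msg, "'times' and 'fraction' must have equal length")
    if (length(object@times) && (any(!is.finite(object@times)) ||
        any(diff(object@times) <= 0) || any(object@times <= 0)))
      msg <- c(msg, "'times' must be positive, finite, strictly increasing")
    if (length(object@sigma) &&
        length(object@sigma) != length(object@times))
      msg <- c(msg, "'sigma' must be empty or match 'times' in length")
    s3 <- if (length(object@sigma)) 3 * max(object@sigma) else 0
    if (length(object@fraction) &&
        (any(object@fraction < -s3 - 1e-12) ||
         any(object@fraction > 1 + s3 + 1e-12)))
      msg <- c(msg, "'fraction' must lie within [0, 1] up to 3 sigma")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ProgressCurve
#'
#' @param times Times (s), strictly increasing.
#' @param fraction Fraction of unliganded molecules at each time.
#' @param sigma Optional per-point noise standard deviation.
#' @return A [ProgressCurve-class] object.
#' @export
ProgressCurve <- function(times, fraction, sigma = numeric(0)) {
  methods::new("ProgressCurve", times = as.numeric(times),
               fraction = as.numeric(fraction), sigma = as.numeric(sigma))
}

## ---------------------------------------------------------------------------

#' TAMap: time-resolved difference-absorption map
#'
#' @slot wavelengths Wavelength axis (nm), strictly increasing.
#' @slot delays Delay axis (s), strictly increasing.
#' @slot deltaA Matrix of differential absorbance, wavelengths in rows and
#'   delays in columns.
#' @export
setClass("TAMap",
  representation(wavelengths = "numeric", delays = "numeric",
                 deltaA = "matrix"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@wavelengths) <= 0))
      msg <- c(msg, "'wavelengths' must be strictly increasing")
    if (length(object@delays) > 1 && any(diff(object@delays) <= 0))
      msg <- c(msg, "'delays' must be strictly increasing")
    if (nrow(object@deltaA) != length(object@wavelengths) ||
        ncol(object@deltaA) != length(object@delays))
      msg <- c(msg, "'deltaA' dimensions must match the axes")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a TAMap
#'
#' @param wavelengths Wavelengths (nm), increasing.
#' @param delays Delays (s), increasing.
#' @param deltaA Differential-absorbance matrix (wavelength x delay).
#' @return A [TAMap-class] object.
#' @export
TAMap <- function(wavelengths, delays, deltaA) {
  methods::new("TAMap", wavelengths = as.numeric(wavelengths),
               delays = as.numeric(delays),
               deltaA = as.matrix(deltaA))
}

#' SVDResult: singular decomposition of a TA map
#'
#' @slot d Singular values (non-increasing, >= 0).
#' @slot u Spectral components (columns, unit norm).
#' @slot v Temporal amplitudes (columns, unit norm).
#' @slot rankSelected Number of significant components at decomposition-time
#'   default thresholds.
#' @export
setClass("SVDResult",
  representation(d = "numeric", u = "matrix", v = "matrix",
                 rankSelected = "integer"),
  validity = function(object) {
    if (any(diff(object@d) > 1e-12) || any(object@d < -1e-12))
      return("singular values must be non-negative and non-increasing")
    TRUE
  }
)

#' LifetimeDistribution: maximum-entropy lifetime spectrum
#'
#' Non-negative amplitude density g(log10 tau) over a uniform log-lifetime
#' grid, such that N(t) is reconstructed as sum_i g_i exp(-t/tau_i) dlog10tau.
#'
#' @slot log10Tau Grid of log10(lifetime / s), uniformly spaced.
#' @slot amplitude Non-negative density at each grid point.
#' @slot lambda Regularization weight at which the solution was accepted.
#' @slot chisqPerPoint Chi-square per data point of the reconstruction.
#' @slot converged TRUE when the chi-square target was bracketed by the
#'   lambda schedule.
#' @export
setClass("LifetimeDistribution",
  representation(log10Tau = "numeric", amplitude = "numeric",
                 lambda = "numeric", chisqPerPoint = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@log10Tau) != length(object@amplitude))
      msg <- c(msg, "grid and amplitudes must have equal length")
    if (any(object@amplitude < 0))
      msg <- c(msg, "amplitudes must be non-negative")
    d <- diff(object@log10Tau)
    if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d)))
      msg <- c(msg, "'log10Tau' must be uniformly increasing")
    if (length(msg)) msg else TRUE
  }
)

## ---------------------------------------------------------------------------

#' FitProblem: a global-fit specification
#'
#' @slot curves List of [ProgressCurve-class] datasets.
#' @slot conditions List of [Condition-class], one per curve (rates are shared
#'   across datasets; only the CO concentration differs).
#' @slot start [MicroRates-class] initial values.
#' @slot free Character vector of free rate labels; all others held fixed.
#' @slot lower,upper Named numeric bounds (s^-1 or M^-1 s^-1) for the free
#'   rates; optimization runs in log10 space within these boxes.
#' @slot topology [SchemeTopology-class] used by the forward model.
#' @export
setClass("FitProblem",
  representation(curves = "list", conditions = "list", start = "MicroRates",
                 free = "character", lower = "numeric", upper = "numeric",
                 topology = "SchemeTopology"),
  validity = function(object) {
    msg <- character()
    if (length(object@curves) < 1L)
      msg <- c(msg, "at least one dataset is required")
    if (length(object@curves) != length(object@conditions))
      msg <- c(msg, "'curves' and 'conditions' must have equal length")
    if (!all(object@free %in% .rateNames))
      msg <- c(msg, "'free' must be MicroRates labels")
    if (length(msg)) msg else TRUE
  }
)

#' FitResult: outcome of a global fit
#'
#' @slot rates Best-fit [MicroRates-class].
#' @slot se Named asymptotic standard errors of the free rates (linear scale).
#' @slot covariance Covariance matrix of the free parameters in log10 space.
#' @slot redChisq Reduced chi-square.
#' @slot residuals List of weighted residual vectors, one per dataset.
#' @slot nonIdentifiable Labels of free parameters flagged as structurally
#'   non-identifiable (near-singular curvature directions).
#' @slot convergence List with iteration count, termination message and the
#'   multi-start chi-square trace.
#' @export
setClass("FitResult",
  representation(rates = "MicroRates", se = "numeric", covariance = "matrix",
                 redChisq = "numeric", residuals = "list",
                 nonIdentifiable = "character", convergence = "list"))

## ---------------------------------------------------------------------------
## show methods

setMethod("show", "CycleParameters", function(object) {
  cat("Proton-linkage cycle (4 species)\n")
  cat(sprintf("  pKa(open) = %.3g   pKa(closed) = %.3g\n",
              object@pkaOpen, object@pkaClosed))
  cat(sprintf("  K_D = %.4g   K_H (derived) = %.4g\n",
              object@kD, kH(object)))
  cat(sprintf("  apparent pKa = %.4g\n", apparentPKa(object)))
})

setMethod("show", "MicroRates", function(object) {
  cat("Microscopic rate constants of the rebinding scheme:\n")
  print(object@rates)
})

setMethod("show", "ProgressCurve", function(object) {
  n <- length(object@times)
  cat(sprintf("Rebinding progress curve: %d points, %.3g - %.3g s%s\n",
              n, object@times[1], object@times[n],
              if (length(object@sigma)) " (with noise sigma)" else ""))
})

setMethod("show", "TAMap", function(object) {
  cat(sprintf("Transient-absorption map: %d wavelengths x %d delays\n",
              length(object@wavelengths), length(object@delays)))
  cat(sprintf("  lambda %.1f - %.1f nm, delay %.3g - %.3g s\n",
              min(object@wavelengths), max(object@wavelengths),
              min(object@delays), max(object@delays)))
})

setMethod("show", "SVDResult", function(object) {
  cat(sprintf("SVD of TA map: %d components, %d significant\n",
              length(object@d), object@rankSelected))
  cat("  singular values:", format(utils::head(object@d, 5), digits = 3),
      if (length(object@d) > 5) "..." else "", "\n")
})

setMethod("show", "LifetimeDistribution", function(object) {
  cat(sprintf(
    "Lifetime distribution: %d points, log10(tau) in [%.1f, %.1f]\n",
    length(object@log10Tau), min(object@log10Tau), max(object@log10Tau)))
  cat(sprintf("  lambda = %.4g, chi2/N = %.3f, converged: %s\n",
              object@lambda, object@chisqPerPoint, object@converged))
})

setMethod("show", "FitResult", function(object) {
  cat("Global fit of the rebinding scheme\n")
  cat(sprintf("  reduced chi-square: %.4g\n", object@redChisq))
  free <- names(object@se)
  est <- object@rates@rates[free]
  for (nm in free)
    cat(sprintf("  %-5s = %.4g +/- %.2g\n", nm, est[[nm]], object@se[[nm]]))
  if (length(object@nonIdentifiable))
    cat("  non-identifiable:",
        paste(object@nonIdentifiable, collapse = ", "), "\n")
})
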