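---
title: "Modelling pH-dependent CO rebinding in nitrophorins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pH-dependent CO rebinding in nitrophorins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nprebind)
```

# Overview

This vignette documents the models behind `nprebind`, the assumptions they
make, the numerical choices, and the known limitations. The package covers
two coupled layers of the nitrophorin story:

1. a **thermodynamic layer** — the proton-linkage cycle that makes ligand
   affinity pH-dependent, and
2. a **kinetic layer** — the microscopic scheme that a photolyzed CO
   molecule traverses on its way back to the heme iron.

# The proton-linkage cycle

A buried aspartate can be protonated (superscript 0) or ionized (−), and the
protein can be closed (C) or open (O), giving four species linked by

* two acid dissociation constants, Ka^C = [C−][H+]/[C0] and
  Ka^O = [O−][H+]/[O0], expressed as microscopic pKa values, and
* two conformational constants, K_D = [O−]/[C−] (ionized) and
  K_H = [O0]/[C0] (protonated).

Going around the cycle must return the free energy to its starting value, so
only three of the four constants are independent: K_D/K_H = Ka^O/Ka^C. The
package enforces this by construction — `CycleParameters` stores
(pKa^O, pKa^C, K_D) and derives K_H with `kH()`, so an inconsistent cycle
cannot be represented.

```{r}
cyc <- CycleParameters(pkaOpen = 4.1, pkaClosed = 6.9, kD = 4)
kH(cyc)
speciesFractions(cyc, c(5.5, 7.5))
```

`speciesFractions()` computes statistical weights in log space before
normalizing (a softmax), so extreme pH or K_D values cannot overflow.

## The apparent pKa and its oracle

The observable midpoint of the pH transition is the **apparent pKa**

pKa_app = pKa^O + pKa^C − log10((K_D + 1) / (K_D·Ka^C + Ka^O)).

Algebraically this is the pH at which the titratable residue is **half
protonated** in the four-state system, i.e. where f(C0) + f(O0) = 1/2. It is
*not* in general the pH at which the protein is half open: the open fraction
crosses 1/2 at a slightly different pH, and never does when K_D < 1 (the
ionized protein then stays mostly closed at any pH) or K_H > 1. The
protonation midpoint is what the closed-form expression describes and what
the conformational transition tracks, so that is the definition the package
adopts; `transitionMidpointPH()` provides an independent numerical oracle by
root-finding on `speciesFractions()`:

```{r}
apparentPKa(cyc)
transitionMidpointPH(cyc)
```

The test suite verifies the two routes agree to 1e-4 pH units over 1000
random cycles (pKa values in [2, 12], K_D in [1e-3, 1e4]).

# The seven-state rebinding scheme

The kinetic states are BOUND (heme-ligated), DP (photolyzed ligand still in
the distal pocket), T2/T3 (back-tunnel docking sites), T4 (a near-pocket
site), SOLV (ligand escaped to solvent; deoxy protein) and RELAX (a slowly
reactive relaxed conformation in exchange with SOLV). Eleven microscopic
constants drive the edges; all are first-order except the solvent re-entry
constant `k_m2` (M⁻¹ s⁻¹), which is multiplied by the CO concentration when
`buildRateMatrix()` assembles the generator matrix A of dp/dt = A·p.
Pseudo-first-order conditions are assumed: [CO] is constant during
rebinding, valid when the protein concentration is far below [CO]
(~1 mM at 1 atm).

Two plausible wirings of the back tunnel exist — a linear chain
DP↔T2↔T3 and a star with T3 attached directly to DP. The published scheme
drawing does not settle this, so `defaultTopology(backTunnel =)` exposes
both; the chain is the default. All shipped rate sets and derived quantities
in this package are insensitive to the choice at the level of the headline
numbers, but fitted docking-site rates are not transferable between the two
wirings.

## Numerical choices

* `simulateRebinding()` integrates the stiff linear system with
  `deSolve::lsoda`, a constant analytic Jacobian, rtol = 1e-10 and
  atol = 1e-16. The rates span 1e2–1e11 s⁻¹, so the problem is stiff over
  most of the 13 decades of time.
* N(t) is computed as the **sum of the unbound-state populations**, not as
  1 − p(BOUND). When N decays to ~1e-6, the subtraction form cancels
  against p(BOUND) ≈ 1 and loses five significant digits; the sum of
  non-negative terms keeps full relative accuracy.
* `engine = "expm"` evaluates the matrix-exponential solution
  (`Matrix::expm`, scaling and squaring) as an independent cross-check. The
  two engines agree to better than 1e-6 relative wherever N ≥ 1e-6; below
  that both routes sit at their accuracy floors (the test suite compares
  only above the floor).
* Population conservation (columns of A sum to zero) holds to 1e-10 along
  every trajectory.

```{r}
rts <- np7Rates("wt", 5.5)
pc <- simulateRebinding(rts, condition = Condition(coAtm = 1),
                        times = logTimeGrid(1e-13, 1, 20))
geminateAmplitude(pc)   # fraction rebound before 10 ns
```

## Effective bimolecular constant

A ligand that re-enters the distal pocket from the solvent rebinds with
probability k₋₁/(k₋₁ + k₂) before it can escape again, so the effective
second-order binding constant is k_on = k₋₂ · k₋₁/(k₋₁ + k₂). The docking
sites are dead ends for this branching and leave it unchanged.
`apparentKonFromSimulation()` cross-checks the closed form by fitting a
single exponential to the decay of the simulated solvent-state population.
The solvent population is used rather than N(t) because N(t) also contains
the slow release from the docking sites, which contaminates a naive tail
fit.

```{r}
effectiveKon(rts) / 1e8
apparentKonFromSimulation(rts, Condition(coConcentration = 1e-3)) / 1e8
```

# Global fitting

`fitScheme()` minimizes the weighted residual sum over all datasets
simultaneously with Levenberg–Marquardt (`minpack.lm::nls.lm`):

* **log10 parameterization** — rates spanning eight orders of magnitude are
  optimized on a scale where relative steps are natural, with box bounds
  (default ±3 decades around the start).
* **deterministic multi-start** — log-normal perturbations of the start
  (seeded; the first start is unperturbed), best chi-square wins.
* **weights** — 1/sigma where per-point sigmas are declared, floored at
  1e-3 of the largest sigma so that fully rebound tail points (sigma → 0)
  cannot dominate; uniform otherwise.
* **uncertainty** — curvature from a central-difference Jacobian; the
  covariance uses an eigenvalue pseudo-inverse, and free parameters loading
  on near-null curvature directions are reported in `nonIdentifiable`
  rather than being silently assigned huge standard errors.

Fitting all 11 rates to a single curve is structurally non-identifiable;
the default frees the in/out/entry trio (`k_m1`, `k_2`, `k_m2`), which the
test suite shows is recovered to <1 % noise-free and within 20 % at 2 %
multiplicative noise.

# Maximum-entropy lifetime inversion

`memInvert()` represents N(t) = Σ g_i·exp(−t/τ_i)·Δlog10τ with g ≥ 0 on a
uniform log10 τ grid and maximizes S − λχ²/2, where S is the Shannon–Jaynes
entropy relative to a flat prior integrating to the curve's decaying
amplitude. Non-negativity is enforced by optimizing log-amplitudes
(L-BFGS-B); λ is tuned by a ladder-plus-bisection schedule until χ² per
point falls in [0.9, 1.1]. Two honest caveats are built in:

* A non-negative mixture of decaying exponentials is a completely monotone
  function, so it **cannot chase noise wiggles**; for unlucky noise draws
  the χ² floor sits slightly above the band, and the closest solution is
  returned with `converged = FALSE` and a warning instead of pretending
  success.
* Entropy smoothing leaves mildly correlated residuals and can deposit a
  small (~2 %) artifact band at a grid edge. `bandPeaks()` reports all
  bands with their areas; downstream analysis should key on the dominant
  bands.

The inversion is deterministic: the same curve, grid and schedule reproduce
the same distribution bit for bit.

# Spectral analysis

* `svdDecompose()` anchors every spectral component positive at 436 nm (the
  photoproduct Soret maximum). A component counts as significant when its
  singular value is ≥ 5 % of the first **and** both its spectral and
  temporal columns have lag-1 autocorrelation ≥ 0.8 — noise columns
  decorrelate, signal columns are smooth.
* `findIsosbestic()` locates zero crossings of the delay-averaged spectrum
  (averaging suppresses noise), requires real amplitude on both flanking
  lobes (rejecting baseline wiggles), and then checks time invariance of
  the map at the crossing across all delays.
* `mergeTimescales()` joins femtosecond and nanosecond curves with a single
  scale factor: least squares over the overlap when there is one,
  single-exponential tail extrapolation across gaps of up to two decades
  otherwise. Wider gaps raise an error rather than inventing a bridge. The
  tail model assumes the fast curve is genuinely single-exponential over
  its last decade; plateaus with slow docking-site release violate that
  assumption, and the overlap route should be used instead.

# Synthetic data

`genProgressCurve()` perturbs a simulated curve with seeded multiplicative
plus additive Gaussian noise (N' = N(1 + σ_m·ε) + σ_a·ε, clipped at zero)
and stores the per-point standard deviation, so generated data declare
their own noise model — the χ² calibration of fits and inversions is then
testable. `genTAMap()` builds rank-1 maps D = s(λ)⊗N(t); the two-band
difference spectrum of `differenceBands()` is solved so that its zero
crossings land exactly at requested wavelengths (defaults 402/426 nm, with
a broad 436-nm photoproduct band and a sharp 416-nm bleach), which makes
the isosbestic detector testable against construction.

Defaults (1 % multiplicative noise for single-wavelength curves, 0.5 % of
peak additive for maps) reflect typical flash-photolysis and broadband
detection quality.

# Open design decisions and limitations

* **Back-tunnel wiring** is user-selectable, as discussed above.
* **The apparent pKa is the protonation midpoint**, not the half-open pH;
  both are computable, only the former has a closed form.
* **Rounding conventions**: `konRatio()` rounds each constant to one
  decimal in 1e8 units before taking the ratio, reproducing arithmetic done
  on tabulated values; `asPercent()` rounds half away from zero as printed
  tables do. Raw values are never rounded elsewhere.
* The scheme is **linear (pseudo-first-order)**: no ligand depletion, no
  protein–protein interactions, no time-dependent rates. Temperature is
  metadata, not a model input — rate sets are valid at the temperature
  they were measured.
* MEM lifetime grids must cover the data's time range (enforced); peak
  positions within ~0.1 log10 units and areas within a few percent are the
  realistic resolution at 1 % noise.
* The fitted covariance is asymptotic (local curvature); strongly
  correlated rate pairs are better judged from `parameterCorrelations()`
  and the non-identifiability flags than from individual standard errors.
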