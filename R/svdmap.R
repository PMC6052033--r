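## SVD analysis of time-resolved difference-absorption maps, isosbestic-point
## detection, and merging of femtosecond and nanosecond kinetics.

.lag1Autocorr <- function(x) {
  x <- x - mean(x)
  d <- sum(x^2)
  if (d <= 0) return(0)
  sum(x[-1] * x[-length(x)]) / d
}

#' Singular value decomposition of a TA map
#'
#' Exact SVD of the difference-absorbance matrix, with the sign convention
#' that every spectral component is positive at the reference wavelength
#' (default 436 nm, the photoproduct Soret maximum and the usual
#' single-wavelength monitoring position), which makes the temporal
#' amplitudes directly comparable to single-wavelength kinetics.
#'
#' @param map A [TAMap-class] with no missing values.
#' @param refWavelength Reference wavelength (nm) anchoring the sign.
#' @param svRatioFloor,autocorrFloor Thresholds forwarded to
#'   [significantComponents()] when stamping `rankSelected`.
#' @return An [SVDResult-class].
#' @export
svdDecompose <- function(map, refWavelength = 436,
                         svRatioFloor = 0.05, autocorrFloor = 0.8) {
  methods::validObject(map)
  if (any(!is.finite(map@deltaA)))
    stop("map contains missing or non-finite values; interpolate first",
         call. = FALSE)
  s <- svd(map@deltaA)
  iref <- which.min(abs(map@wavelengths - refWavelength))
  for (j in seq_along(s$d)) {
    if (s$u[iref, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  res <- methods::new("SVDResult", d = s$d, u = s$u, v = s$v,
                      rankSelected = 0L)
  res@rankSelected <- significantComponents(res, svRatioFloor, autocorrFloor)
  res
}

#' Count the significant SVD components
#'
#' A component is significant when its singular value is at least
#' `svRatioFloor` times the first AND the lag-1 autocorrelations of both its
#' spectral and temporal columns reach `autocorrFloor` (noise columns
#' decorrelate, signal columns are smooth).
#'
#' @param res An [SVDResult-class].
#' @param svRatioFloor Singular-value floor relative to the largest
#'   (default 0.05).
#' @param autocorrFloor Lag-1 autocorrelation floor (default 0.8).
#' @return Integer count.
#' @export
significantComponents <- function(res, svRatioFloor = 0.05,
                                  autocorrFloor = 0.8) {
  if (length(res@d) == 0L || res@d[1] <= 0) return(0L)
  keep <- vapply(seq_along(res@d), function(j) {
    res@d[j] >= svRatioFloor * res@d[1] &&
      .lag1Autocorr(res@u[, j]) >= autocorrFloor &&
      .lag1Autocorr(res@v[, j]) >= autocorrFloor
  }, logical(1))
  sum(keep)
}

#' Time course of an SVD component scaled to the map's amplitude
#'
#' Rescales the temporal amplitude V_j to the map's differential absorbance
#' at the reference wavelength: trace(t) = d_j * U_j(ref) * V_j(t). For a
#' rank-1 map this reproduces the single-wavelength slice exactly.
#'
#' @param res An [SVDResult-class].
#' @param index Component index (must not exceed the selected rank).
#' @param map The decomposed [TAMap-class].
#' @param refWavelength Reference wavelength in nm (default 436).
#' @return A data.frame with columns `delay` and `trace`.
#' @export
componentKinetics <- function(res, index, map, refWavelength = 436) {
  if (index < 1L || index > res@rankSelected)
    stop("component index ", index, " exceeds the selected rank (",
         res@rankSelected, ")", call. = FALSE)
  iref <- which.min(abs(map@wavelengths - refWavelength))
  data.frame(delay = map@delays,
             trace = res@d[index] * res@u[iref, index] * res@v[, index])
}

#' Detect isosbestic points in a TA map
#'
#' An isosbestic point is a wavelength where the differential absorbance is
#' zero at every delay, the signature of a clean two-species interconversion.
#' Zero crossings are located per delay by linear interpolation between
#' adjacent wavelengths, clustered across delays (gap > 1 nm starts a new
#' cluster), and a cluster is reported when it is present at every delay,
#' has sub-nm spread, and the map amplitude at the crossing stays below
#' `tolerance` times the global maximum.
#'
#' @param map A [TAMap-class] with at least 3 delays.
#' @param tolerance Amplitude tolerance relative to max |deltaA| (default
#'   0.02).
#' @return Numeric vector of isosbestic wavelengths (possibly empty).
#' @export
findIsosbestic <- function(map, tolerance = 0.02) {
  methods::validObject(map)
  nd <- length(map@delays)
  if (nd < 3L)
    stop("need at least 3 delays to establish time invariance", call. = FALSE)
  wl <- map@wavelengths
  maxAbs <- max(abs(map@deltaA))
  if (maxAbs == 0) return(numeric(0))
  ## zero crossings of the delay-averaged spectrum (noise averages out),
  ## including exact on-grid zeros
  sbar <- rowMeans(map@deltaA)
  n <- length(sbar)
  a <- sbar[-n]; b <- sbar[-1]
  i <- which(a * b < 0 | (a != 0 & b == 0))
  if (length(i) == 0L) return(numeric(0))
  x <- wl[i] - a[i] * (wl[i + 1] - wl[i]) / (b[i] - a[i])
  ## each crossing must separate lobes of real amplitude (rejects wiggles in
  ## the baseline wings) and be time-invariant within tolerance
  smax <- max(abs(sbar))
  edges <- c(min(wl), x, max(wl))   # x is increasing by construction
  lobeMax <- vapply(seq_len(length(edges) - 1L), function(k)
    max(abs(sbar[wl >= edges[k] & wl <= edges[k + 1L]])), numeric(1))
  out <- numeric(0)
  for (k in seq_along(x)) {
    if (lobeMax[k] < 2 * tolerance * smax ||
        lobeMax[k + 1L] < 2 * tolerance * smax) next
    timeInv <- all(vapply(seq_len(nd), function(j)
      abs(.interpWl(wl, map@deltaA[, j], x[k])) <= tolerance * maxAbs,
      logical(1)))
    if (timeInv) out <- c(out, x[k])
  }
  out
}

.interpWl <- function(wl, y, x) stats::approx(wl, y, xout = x, rule = 2)$y

#' Merge femtosecond and nanosecond rebinding curves
#'
#' Joins a picosecond-timescale curve with a nanosecond/flash-photolysis
#' curve into one progress curve. The nanosecond branch is multiplied by a
#' single factor chosen so that it matches the femtosecond branch: over an
#' overlap region the factor is the least-squares amplitude ratio; across a
#' gap the femtosecond tail (single exponential fitted to its last decade)
#' is extrapolated to the first nanosecond point. Gaps wider than two decades
#' cannot be bridged by the tail model and raise an error.
#'
#' @param fsCurve,nsCurve [ProgressCurve-class] objects, both normalized to
#'   the fraction-unliganded convention; `fsCurve` must start first.
#' @return A list with elements `curve` (the merged [ProgressCurve-class])
#'   and `scale` (the factor applied to the nanosecond branch).
#' @export
mergeTimescales <- function(fsCurve, nsCurve) {
  methods::validObject(fsCurve); methods::validObject(nsCurve)
  ft <- fsCurve@times; fN <- fsCurve@fraction
  nt <- nsCurve@times; nN <- nsCurve@fraction
  fEnd <- ft[length(ft)]
  if (nt[1] <= fEnd) {
    ## overlap: least-squares scale on the common window
    sel <- nt >= ft[1] & nt <= fEnd
    fsOn <- .interpLogTime(ft, fN, nt[sel])
    scale <- sum(fsOn * nN[sel]) / sum(nN[sel]^2)
  } else {
    gap <- log10(nt[1]) - log10(fEnd)
    if (gap > 2)
      stop("gap between branches exceeds two decades; no tail model applies",
           call. = FALSE)
    ## single-exponential tail over the fs curve's last decade
    tail <- ft >= fEnd / 10 & fN > 0
    if (sum(tail) < 3L)
      stop("too few positive points in the femtosecond tail", call. = FALSE)
    fit <- stats::lm(log(fN[tail]) ~ ft[tail])
    extrap <- exp(sum(stats::coef(fit) * c(1, nt[1])))
    scale <- extrap / nN[1]
  }
  keep <- nt > fEnd
  merged <- ProgressCurve(c(ft, nt[keep]), c(fN, scale * nN[keep]))
  list(curve = merged, scale = scale)
}
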