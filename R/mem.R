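## Maximum-entropy inversion of rebinding progress curves into lifetime
## distributions. The curve is modelled as a superposition of exponentials,
##   N(t) = sum_i g_i exp(-t / tau_i) * dlog10(tau),
## with non-negative density g on a uniform log10(tau) grid. The solution
## maximizes S - lambda * chi^2 / 2, where S is the Shannon-Jaynes entropy
## relative to a flat prior m, and lambda is tuned by bisection so that
## chi^2 per point hits 1 (the classical MEM stopping rule). Non-negativity
## is enforced by optimizing log-amplitudes.

.memKernel <- function(times, log10Tau) {
  dlt <- log10Tau[2] - log10Tau[1]
  exp(-outer(times, 10^log10Tau, "/")) * dlt
}

## one MEM solve at fixed lambda; returns list(g, chisqPerPoint, u).
## Log-amplitudes are clamped (e^40 dwarfs any physical amplitude) so the
## objective stays finite, and the optimizer is restarted until the objective
## stops improving: a single L-BFGS-B run can under-converge at large lambda,
## which would break the monotonicity of chi^2(lambda) that the bisection
## relies on.
.memSolve <- function(u0, K, N, w, m, lambda, maxit = 2000, restarts = 6) {
  n <- length(N)
  fn <- function(u) {
    g <- exp(pmin(u, 40))
    r <- N - as.numeric(K %*% g)
    chisq <- sum(w * r^2)
    S <- sum(g - m - g * (u - log(m)))
    0.5 * lambda * chisq - S
  }
  gr <- function(u) {
    g <- exp(pmin(u, 40))
    r <- N - as.numeric(K %*% g)
    dchi <- -2 * as.numeric(crossprod(K, w * r))
    g * (0.5 * lambda * dchi + (u - log(m)))
  }
  par <- u0
  val <- Inf
  for (i in seq_len(restarts)) {
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e5))
    par <- opt$par
    if (val - opt$value <= 1e-9 * (abs(val) + 1)) { val <- opt$value; break }
    val <- opt$value
  }
  g <- exp(pmin(par, 40))
  r <- N - as.numeric(K %*% g)
  list(g = g, chisqPerPoint = sum(w * r^2) / n, u = par)
}

#' Invert a progress curve into a lifetime distribution
#'
#' Maximum-entropy inversion of N(t) into a non-negative amplitude density
#' over log10(lifetime). The flat prior integrates to the total decaying
#' amplitude of the curve, and the regularization weight is adjusted by
#' bisection until the reconstruction's chi-square per point falls in
#' `chisqBand`. The optimizer is deterministic: the same curve, grid and
#' lambda schedule reproduce the same distribution bit for bit.
#'
#' @param curve A [ProgressCurve-class].
#' @param gridRange Lifetime grid limits as log10(seconds); default
#'   `c(-13, 0)`.
#' @param pointsPerDecade Grid density (default 20).
#' @param sigma Noise scale: a single value or a per-point vector; defaults
#'   to the curve's own sigma field when present.
#' @param chisqBand Acceptance band for chi-square per point (default
#'   `c(0.9, 1.1)`).
#' @return A [LifetimeDistribution-class]. When the chi-square target cannot
#'   be bracketed by the lambda schedule the closest solution is returned
#'   with `converged = FALSE` and a warning.
#' @examples
#' t <- logTimeGrid(1e-12, 1e-6, 15)
#' crv <- ProgressCurve(t, exp(-t / 1e-9))
#' d <- memInvert(crv, gridRange = c(-12, -6), sigma = 0.01)
#' bandPeaks(d)
#' @export
memInvert <- function(curve, gridRange = c(-13, 0), pointsPerDecade = 20,
                      sigma = NULL, chisqBand = c(0.9, 1.1)) {
  methods::validObject(curve)
  if (is.null(sigma)) sigma <- curve@sigma
  if (length(sigma) == 0L)
    stop("'sigma' is required (scalar or per-point noise scale)",
         call. = FALSE)
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop("'sigma' must be positive and finite", call. = FALSE)
  t <- curve@times; N <- curve@fraction
  if (log10(t[1]) < gridRange[1] - 1 ||
      log10(t[length(t)]) > gridRange[2] + 1)
    stop("curve times extend more than a decade beyond the lifetime grid",
         call. = FALSE)
  nPts <- max(2L, round(diff(gridRange) * pointsPerDecade) + 1L)
  log10Tau <- seq(gridRange[1], gridRange[2], length.out = nPts)
  dlt <- log10Tau[2] - log10Tau[1]
  K <- .memKernel(t, log10Tau)
  w <- 1 / rep_len(sigma, length(t))^2

  A <- max(N[1] - N[length(N)], 1e-6)   # total decaying amplitude
  m <- A / (nPts * dlt)                 # flat prior integrating to A
  u0 <- rep(log(m), nPts)

  ## bracket the chi^2 target on a log-lambda ladder, then bisect
  target <- 1
  evalAt <- function(loglam, u0) .memSolve(u0, K, N, w, m, 10^loglam)
  loglam <- 0
  sol <- evalAt(loglam, u0)
  dir <- if (sol$chisqPerPoint > target) 1 else -1
  lo <- hi <- loglam; solLo <- solHi <- sol
  bracketed <- FALSE
  for (i in 1:14) {
    loglam <- loglam + dir
    s2 <- evalAt(loglam, sol$u)
    if ((s2$chisqPerPoint - target) * (sol$chisqPerPoint - target) <= 0) {
      lo <- min(loglam, loglam - dir); hi <- max(loglam, loglam - dir)
      solLo <- if (dir > 0) sol else s2
      solHi <- if (dir > 0) s2 else sol
      bracketed <- TRUE
      sol <- s2
      break
    }
    sol <- s2
    if (abs(s2$chisqPerPoint - target) <=
        max(chisqBand[2] - 1, 1 - chisqBand[1])) {
      bracketed <- TRUE; lo <- hi <- loglam; break
    }
  }
  best <- sol
  if (bracketed && lo < hi) {
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      s2 <- evalAt(mid, best$u)
      best <- s2
      if (s2$chisqPerPoint >= chisqBand[1] &&
          s2$chisqPerPoint <= chisqBand[2]) { lo <- hi <- mid; break }
      ## chi^2 decreases with lambda: too high -> raise lambda
      if (s2$chisqPerPoint > target) lo <- mid else hi <- mid
    }
    loglam <- if (lo == hi) lo else (lo + hi) / 2
  }
  conv <- best$chisqPerPoint >= chisqBand[1] &&
          best$chisqPerPoint <= chisqBand[2]
  if (!conv)
    warning("chi-square target not reached (chi2/N = ",
            format(best$chisqPerPoint, digits = 3),
            "); returning closest solution", call. = FALSE)
  methods::new("LifetimeDistribution", log10Tau = log10Tau,
               amplitude = best$g, lambda = 10^loglam,
               chisqPerPoint = best$chisqPerPoint, converged = conv)
}

#' Reconstruct a progress curve from a lifetime distribution
#'
#' @param dist A [LifetimeDistribution-class].
#' @param times Times (s) at which to evaluate the reconstruction.
#' @return Numeric vector N(t).
#' @export
reconstructCurve <- function(dist, times) {
  as.numeric(.memKernel(times, dist@log10Tau) %*% dist@amplitude)
}

#' Locate bands in a lifetime distribution
#'
#' Segments the distribution at local minima, merges bands whose area falls
#' below `minArea` of the total into their neighbour across the shallower
#' minimum, and reports each surviving band's peak position (refined by
#' quadratic interpolation through the three points around the maximum) and
#' integrated area.
#'
#' @param dist A [LifetimeDistribution-class].
#' @param minArea Minimum band area as a fraction of the total (default
#'   0.02).
#' @return A data.frame with columns `peakLog10Tau` and `area`, sorted by
#'   lifetime; zero rows when the distribution is empty.
#' @export
bandPeaks <- function(dist, minArea = 0.02) {
  g <- dist@amplitude
  lt <- dist@log10Tau
  dlt <- lt[2] - lt[1]
  total <- sum(g) * dlt
  empty <- data.frame(peakLog10Tau = numeric(0), area = numeric(0))
  if (total <= 0 || max(g) <= 0) return(empty)
  ## boundaries at interior local minima
  n <- length(g)
  isMin <- c(FALSE, g[2:(n - 1)] <= g[1:(n - 2)] &
                    g[2:(n - 1)] <= g[3:n], FALSE)
  bounds <- c(0L, which(isMin), n)
  segs <- cbind(utils::head(bounds, -1) + 1L, bounds[-1])
  segs <- segs[segs[, 1] <= segs[, 2], , drop = FALSE]
  area <- apply(segs, 1L, function(s) sum(g[s[1]:s[2]]) * dlt)
  ## merge sub-threshold bands into the neighbour across the shallower edge
  while (nrow(segs) > 1L && min(area) < minArea * total) {
    i <- which.min(area)
    leftDepth <- if (i > 1L) g[segs[i, 1] - 1L] else -Inf
    rightDepth <- if (i < nrow(segs)) g[segs[i, 2] + 1L] else -Inf
    j <- if (leftDepth >= rightDepth) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    segs[a, 2] <- segs[b, 2]
    segs <- segs[-b, , drop = FALSE]
    area <- apply(segs, 1L, function(s) sum(g[s[1]:s[2]]) * dlt)
  }
  if (nrow(segs) == 1L && area[1] < minArea * total) return(empty)
  peaks <- apply(segs, 1L, function(s) {
    idx <- s[1]:s[2]
    k <- idx[which.max(g[idx])]
    if (k > 1L && k < n) {
      y1 <- g[k - 1L]; y2 <- g[k]; y3 <- g[k + 1L]
      den <- y1 - 2 * y2 + y3
      off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
      lt[k] + max(-0.5, min(0.5, off)) * dlt
    } else lt[k]
  })
  out <- data.frame(peakLog10Tau = peaks, area = area)
  out[order(out$peakLog10Tau), , drop = FALSE]
}
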