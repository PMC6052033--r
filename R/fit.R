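## Global nonlinear least-squares fitting of the rebinding scheme to progress
## curves measured at multiple CO concentrations. Rates are shared across
## datasets; only the CO concentration differs. Parameters are optimized in
## log10 space within box bounds (positivity plus the 1e3-1e10 s^-1 scale
## disparity), with deterministic multi-start to escape the local minima of
## multi-phasic schemes.

#' Construct a FitProblem
#'
#' @param curves List of [ProgressCurve-class] datasets (or a single curve).
#' @param conditions List of [Condition-class], one per curve.
#' @param start [MicroRates-class] initial values; fixed parameters keep
#'   these values.
#' @param free Character vector of rate labels to optimize (default the
#'   in/out/entry trio `k_m1`, `k_2`, `k_m2`).
#' @param lower,upper Optional named bounds for the free rates (linear
#'   scale); default `start/1e3` and `start*1e3`.
#' @param topology A [SchemeTopology-class].
#' @return A [FitProblem-class] object.
#' @export
fitProblem <- function(curves, conditions, start,
                       free = c("k_m1", "k_2", "k_m2"),
                       lower = NULL, upper = NULL,
                       topology = defaultTopology()) {
  if (methods::is(curves, "ProgressCurve")) curves <- list(curves)
  if (methods::is(conditions, "Condition")) conditions <- list(conditions)
  s <- start@rates[free]
  if (any(s <= 0))
    stop("free parameters need positive starting values", call. = FALSE)
  if (is.null(lower)) lower <- s / 1e3
  if (is.null(upper)) upper <- s * 1e3
  methods::new("FitProblem", curves = curves, conditions = conditions,
               start = start, free = free,
               lower = stats::setNames(as.numeric(lower[free]), free),
               upper = stats::setNames(as.numeric(upper[free]), free),
               topology = topology)
}

## weighted residual vector over all datasets for free rates given in log10
.fitResiduals <- function(logPar, problem, weights) {
  r <- problem@start@rates
  r[problem@free] <- 10^logPar
  rts <- methods::new("MicroRates", rates = r)
  unlist(lapply(seq_along(problem@curves), function(i) {
    crv <- problem@curves[[i]]
    model <- simulateRebinding(rts, problem@topology,
                               problem@conditions[[i]], crv@times)
    (model@fraction - crv@fraction) * weights[[i]]
  }), use.names = FALSE)
}

## per-dataset weights: 1/sigma where declared (floored against near-zero
## sigmas in the rebound tail), else uniform on the log-spaced grid
.fitWeights <- function(problem) {
  lapply(problem@curves, function(crv) {
    if (length(crv@sigma)) {
      s <- pmax(crv@sigma, 1e-3 * max(crv@sigma))
      1 / s
    } else rep(1, length(crv@times))
  })
}

#' Globally fit the rebinding scheme to progress curves
#'
#' Minimizes the weighted sum of squared deviations between the scheme's ODE
#' solution and all datasets simultaneously, by Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) on the log10 rates within box bounds. Weights are
#' 1/sigma when per-point sigmas are declared, else uniform (the log-spaced
#' grid already balances decades). A deterministic multi-start (perturbed
#' log-normal starts, chosen by best chi-square) guards against local minima.
#'
#' @param problem A [FitProblem-class] object.
#' @param nStarts Number of starts (default 8; the first is unperturbed).
#' @param perturbSd Standard deviation (log10 units) of start perturbations.
#' @param seed Integer seed making the start set reproducible.
#' @param maxIter Iteration cap per start.
#' @return A [FitResult-class] object.
#' @examples
#' \donttest{
#' rts <- np7Rates("wt", 7.5)
#' tg <- logTimeGrid(1e-13, 0.1, 8)
#' cond <- Condition(coAtm = 1)
#' crv <- simulateRebinding(rts, condition = cond, times = tg)
#' start <- MicroRates(k_m1 = 1.2e10, k_2 = 1.8e9, k_m2 = 1.2e8,
#'                     k_3 = 2e3, k_m3 = 1.2e3, k_c = 3.7e9, k_mc = 1.4e9,
#'                     k_d = 1.6e8, k_md = 1.4e4, k_e = 4.5e10, k_me = 2.5e10)
#' fit <- fitScheme(fitProblem(crv, cond, start), nStarts = 2)
#' rates(fit)[c("k_m1", "k_2", "k_m2")]
#' }
#' @export
fitScheme <- function(problem, nStarts = 8, perturbSd = 0.3, seed = 1,
                      maxIter = 100) {
  methods::validObject(problem)
  weights <- .fitWeights(problem)
  lo <- log10(problem@lower); hi <- log10(problem@upper)
  start0 <- log10(problem@start@rates[problem@free])
  starts <- withr::with_seed(seed, {
    lapply(seq_len(nStarts), function(i) {
      if (i == 1L) start0
      else pmin(pmax(start0 + stats::rnorm(length(start0), 0, perturbSd),
                     lo), hi)
    })
  })
  best <- NULL; trace <- numeric(nStarts)
  for (i in seq_len(nStarts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], lower = lo, upper = hi,
        fn = .fitResiduals, problem = problem, weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = maxIter,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    trace[i] <- if (is.null(fit)) NA_real_ else fit$deviance
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("no start converged within the iteration cap", call. = FALSE)

  par <- stats::setNames(best$par, problem@free)
  nfree <- length(par)
  resid <- .fitResiduals(par, problem, weights)
  npts <- length(resid)
  redChisq <- sum(resid^2) / max(1L, npts - nfree)

  ## curvature from a central-difference Jacobian of the weighted residuals
  h <- 1e-5
  J <- vapply(seq_len(nfree), function(j) {
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    (.fitResiduals(pp, problem, weights) -
       .fitResiduals(pm, problem, weights)) / (2 * h)
  }, numeric(npts))
  H <- crossprod(J)
  eg <- eigen(H, symmetric = TRUE)
  tolEv <- max(eg$values) * 1e-10
  sing <- eg$values < tolEv
  nonIdent <- character(0)
  if (any(sing)) {
    load <- abs(eg$vectors[, sing, drop = FALSE])
    nonIdent <- problem@free[apply(load, 1L, max) > 0.3]
  }
  ## pseudo-inverse keeps the fit usable when some directions are flat
  inv <- eg$vectors %*% diag(ifelse(sing, 0, 1 / pmax(eg$values, tolEv)),
                             nfree) %*% t(eg$vectors)
  covLog <- redChisq * inv
  dimnames(covLog) <- list(problem@free, problem@free)
  kHat <- 10^par
  seLin <- kHat * log(10) * sqrt(pmax(diag(covLog), 0))

  r <- problem@start@rates
  r[problem@free] <- kHat
  residList <- split(resid, rep(seq_along(problem@curves),
                                vapply(problem@curves,
                                       function(c) length(c@times),
                                       integer(1))))
  methods::new("FitResult",
               rates = methods::new("MicroRates", rates = r),
               se = stats::setNames(seLin, problem@free),
               covariance = covLog,
               redChisq = redChisq,
               residuals = unname(residList),
               nonIdentifiable = nonIdent,
               convergence = list(iterations = best$niter,
                                  message = best$message,
                                  startChisq = trace))
}

#' Correlation matrix of the fitted parameters
#'
#' @param result A [FitResult-class] from [fitScheme()].
#' @return Symmetric correlation matrix (diagonal 1) of the free parameters.
#' @export
parameterCorrelations <- function(result) {
  v <- result@covariance
  d <- diag(v)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("singular curvature: correlations undefined for ",
         paste(names(d)[!is.finite(d) | d <= 0], collapse = ", "),
         call. = FALSE)
  stats::cov2cor(v)
}
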