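## Parameter recovery protocol: simulate with the tabulated rates, start the
## optimizer with the FREE rates displaced (x2) and the fixed ones at truth.

freeTrio <- c("k_m1", "k_2", "k_m2")

displacedStart <- function(truth, free = freeTrio, factor = 2) {
  r <- truth@rates
  r[free] <- r[free] * factor
  methods::new("MicroRates", rates = r)
}

test_that("noise-free recovery is better than 1 percent for every fixture", {
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-13, 1, 10)
  for (rts in allFixtures()) {
    crv <- simulateRebinding(rts, condition = cond, times = t)
    fit <- fitScheme(fitProblem(crv, cond, displacedStart(rts)), nStarts = 1)
    rel <- abs(rates(fit)[freeTrio] / rts@rates[freeTrio] - 1)
    expect_lt(max(rel), 0.01)
  }
})

test_that("free rates are recovered within 20 percent under 2 percent noise, 10 seeds", {
  rts <- np7Rates("wt", 5.5)
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-13, 1, 10)
  for (seed in 1:10) {
    crv <- trimCurve(genProgressCurve(rts, cond, t,
                                      noise = noiseModel(0.02, 0, seed)))
    fit <- fitScheme(fitProblem(crv, cond, displacedStart(rts)), nStarts = 2)
    rel <- abs(rates(fit)[freeTrio] / rts@rates[freeTrio] - 1)
    expect_lt(max(rel), 0.20)
    ## chi-square calibration: declared sigmas describe the residuals
    expect_gt(fit@redChisq, 0.5)
    expect_lt(fit@redChisq, 2)
  }
})

test_that("multi-dataset fits are invariant to dataset order", {
  rts <- np7Rates("wt", 7.5)
  conds <- list(Condition(coAtm = 1), Condition(coAtm = 0.1))
  t <- logTimeGrid(1e-13, 1, 8)
  curves <- lapply(conds, function(cd)
    simulateRebinding(rts, condition = cd, times = t))
  f1 <- fitScheme(fitProblem(curves, conds, displacedStart(rts)), nStarts = 1)
  f2 <- fitScheme(fitProblem(rev(curves), rev(conds), displacedStart(rts)),
                  nStarts = 1)
  expect_equal(rates(f1)[freeTrio], rates(f2)[freeTrio], tolerance = 1e-6)
})

test_that("correlation matrix is well formed", {
  rts <- np7Rates("wt", 5.5)
  cond <- Condition(coAtm = 1)
  crv <- trimCurve(genProgressCurve(rts, cond, logTimeGrid(1e-13, 1, 10),
                                    noise = noiseModel(0.02, 0, 3)))
  fit <- fitScheme(fitProblem(crv, cond, displacedStart(rts)), nStarts = 1)
  C <- parameterCorrelations(fit)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_equal(C, t(C))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_true(all(fit@se > 0))
})

test_that("a parameter with no kinetic influence is flagged non-identifiable", {
  rts <- np7Rates("wt", 5.5)
  r <- rts@rates; r[["k_d"]] <- 0   # T4 never populated -> k_md has no effect
  truth <- methods::new("MicroRates", rates = r)
  cond <- Condition(coAtm = 1)
  crv <- simulateRebinding(truth, condition = cond,
                           times = logTimeGrid(1e-13, 1, 8))
  prob <- fitProblem(crv, cond, truth, free = c(freeTrio, "k_md"))
  fit <- fitScheme(prob, nStarts = 1)
  expect_true("k_md" %in% fit@nonIdentifiable)
  expect_error(parameterCorrelations(fit), "k_md")
})

test_that("fitProblem validates its inputs", {
  rts <- np7Rates("wt", 5.5)
  cond <- Condition(coAtm = 1)
  crv <- simulateRebinding(rts, condition = cond,
                           times = logTimeGrid(1e-12, 1e-6, 5))
  r <- rts@rates; r[["k_3"]] <- 0
  zero <- methods::new("MicroRates", rates = r)
  expect_error(fitProblem(crv, cond, zero, free = c("k_3")), "positive")
})
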