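test_that("rate matrix conserves mass and scales only the re-entry edge with [CO]", {
  rts <- np7Rates("wt", 5.5)
  A1 <- buildRateMatrix(rts, condition = Condition(coAtm = 1))
  expect_equal(max(abs(colSums(A1))), 0, tolerance = 1e-12)
  offDiag <- A1; diag(offDiag) <- 0
  expect_true(all(offDiag >= 0))
  ## absorbing bound state: nothing leaves BOUND
  expect_true(all(A1[-match("BOUND", rownames(A1)), "BOUND"] == 0))
  A2 <- buildRateMatrix(rts, condition = Condition(coConcentration = 2e-3))
  d <- A2 - A1
  diag(d) <- 0
  nz <- which(d != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(rownames(A1)[nz[1, "row"]], "DP")
  expect_equal(colnames(A1)[nz[1, "col"]], "SOLV")
  expect_equal(A2["DP", "SOLV"], rts@rates[["k_m2"]] * 2e-3)
})

test_that("simulation matches the two-state closed forms", {
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-12, 1e-8, 40)
  ## pure rebinding: N(t) = exp(-k_m1 t)
  pc <- simulateRebinding(MicroRates(k_m1 = 5e9), condition = cond, times = t)
  expect_equal(pc@fraction, exp(-5e9 * t), tolerance = 1e-8)
  ## rebinding vs escape: N(t) -> k_2/(k_m1+k_2) plateau
  pc2 <- simulateRebinding(MicroRates(k_m1 = 5e9, k_2 = 2e9),
                           condition = Condition(coConcentration = 1e-12),
                           times = t)
  ref <- 1 - 5e9 / 7e9 * (1 - exp(-7e9 * t))
  expect_equal(pc2@fraction, ref, tolerance = 1e-8)
})

test_that("population is conserved to 1e-10 in all fixture simulations", {
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-13, 1, 10)
  for (rts in allFixtures()) {
    sim <- simulateRebinding(rts, condition = cond, times = t, full = TRUE)
    expect_lt(max(abs(rowSums(sim$populations) - 1)), 1e-10)
    expect_true(all(sim$populations > -1e-12))
  }
})

test_that("stiff integrator agrees with the matrix-exponential oracle on 50 random rate sets", {
  withr::local_seed(99)
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-13, 1e-2, 6)
  for (i in 1:50) {
    rts <- randomRates()
    nOde <- simulateRebinding(rts, condition = cond, times = t)@fraction
    nExp <- simulateRebinding(rts, condition = cond, times = t,
                              engine = "expm")@fraction
    sel <- nExp >= 1e-6   # below this both engines sit at their atol floor
    expect_lt(max(abs(nOde[sel] - nExp[sel]) / nExp[sel]), 1e-6)
  }
})

test_that("effective k_on reproduces the tabulated constants and ratios", {
  expect_equal(signif(effectiveKon(np7Rates("wt", 5.5)) / 1e8, 2), 1.5)
  expect_equal(konRatio(np7Rates("wt", 5.5), np7Rates("wt", 7.5)), 3)
  expect_equal(konRatio(np7Rates("E27V", 5.5), np7Rates("E27V", 7.5)), 2.2)
  ## E27Q: pH-insensitive entry, unrounded ratio ~1.2 rounds to 1
  rq <- effectiveKon(np7Rates("E27Q", 5.5)) / effectiveKon(np7Rates("E27Q", 7.5))
  expect_equal(round(rq), 1)
})

test_that("effective k_on agrees with a forward-simulated bimolecular phase", {
  rts <- np7Rates("wt", 5.5)
  cond <- Condition(coConcentration = 1e-3)
  kSim <- apparentKonFromSimulation(rts, cond)
  expect_lt(abs(kSim - effectiveKon(rts)) / effectiveKon(rts), 0.05)
  expect_equal(signif(kSim / 1e8, 2), 1.5)
})

test_that("geminate amplitude of the acidic wild type falls in the reported bracket", {
  pc <- simulateRebinding(np7Rates("wt", 5.5), condition = Condition(coAtm = 1),
                          times = logTimeGrid(1e-13, 1, 20))
  g <- geminateAmplitude(pc)
  expect_gte(g, 0.90)
  expect_lte(g, 0.97)
  expect_error(geminateAmplitude(pc, tSplit = 10), "outside")
})

test_that("both back-tunnel wirings simulate and conserve mass", {
  cond <- Condition(coAtm = 1)
  t <- logTimeGrid(1e-13, 1e-3, 8)
  rts <- np7Rates("wt", 7.5)
  for (bt in c("T2-T3", "DP-T3")) {
    topo <- defaultTopology(backTunnel = bt)
    sim <- simulateRebinding(rts, topo, cond, t, full = TRUE)
    expect_lt(max(abs(rowSums(sim$populations) - 1)), 1e-10)
  }
  ## the wiring changes the kinetics
  n1 <- simulateRebinding(rts, defaultTopology("T2-T3"), cond, t)@fraction
  n2 <- simulateRebinding(rts, defaultTopology("DP-T3"), cond, t)@fraction
  expect_gt(max(abs(n1 - n2)), 1e-4)
})

test_that("simulation input validation", {
  rts <- np7Rates("wt", 5.5)
  cond <- Condition(coAtm = 1)
  expect_error(simulateRebinding(rts, condition = cond, times = c(1, 1)),
               "strictly increasing")
  expect_error(simulateRebinding(rts, condition = cond, times = c(0, 1)),
               "positive")
  expect_error(np7Rates("wt", 6.0))
})
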