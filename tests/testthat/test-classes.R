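test_that("ProgressCurve enforces its invariants", {
  expect_error(ProgressCurve(c(1, 1, 2) * 1e-9, c(1, 0.5, 0.2)),
               "strictly increasing")
  expect_error(ProgressCurve(c(-1, 1) * 1e-9, c(1, 0.5)), "positive")
  expect_error(ProgressCurve(1e-9, 1.5), "3 sigma")
  ## noisy excursions above 1 are legal within 3 sigma
  crv <- ProgressCurve(c(1e-9, 1e-8), c(1.02, 0.5), c(0.01, 0.01))
  expect_s4_class(crv, "ProgressCurve")
  expect_error(ProgressCurve(c(1e-9, 1e-8), c(1.05, 0.5), c(0.01, 0.01)),
               "3 sigma")
  expect_error(ProgressCurve(c(1e-9, 1e-8), c(1, 0.5), 0.01), "length")
})

test_that("MicroRates validates names and signs", {
  expect_error(MicroRates(k_m1 = -1), ">= 0|> 0")
  expect_error(MicroRates(k_m1 = 0), "> 0")
  expect_error(methods::new("MicroRates", rates = c(a = 1)), "named exactly")
  r <- MicroRates(k_m1 = 1e10)
  expect_equal(sum(r@rates), 1e10)
})

test_that("Condition converts pressure via Henry's law", {
  expect_equal(Condition(coAtm = 1)@coConcentration, 1e-3)
  expect_equal(Condition(coAtm = 0.1)@coConcentration, 1e-4)
  expect_equal(Condition(coConcentration = 5e-4)@coConcentration, 5e-4)
  expect_error(Condition(), "either")
  expect_error(Condition(coConcentration = 0), "> 0")
  expect_error(Condition(coAtm = 1, photolyzedFraction = 2), "\\(0, 1\\]")
})

test_that("SchemeTopology rejects malformed wirings", {
  topo <- defaultTopology()
  bad <- topo@edges
  bad$from[1] <- "BOUND"
  expect_error(methods::new("SchemeTopology", states = topo@states,
                            edges = bad), "absorbing")
  dup <- rbind(topo@edges, topo@edges[1, ])
  expect_error(methods::new("SchemeTopology", states = topo@states,
                            edges = dup), "exactly one edge")
})

test_that("TAMap checks axis/matrix consistency", {
  expect_error(TAMap(1:3, 1:2, matrix(0, 2, 2)), "dimensions")
  expect_error(TAMap(c(2, 1, 3), 1:2, matrix(0, 3, 2)), "increasing")
})

test_that("accessors return the underlying slots", {
  t <- logTimeGrid(1e-12, 1e-9, 4)
  crv <- ProgressCurve(t, exp(-t / 1e-10), rep(0.01, length(t)))
  expect_identical(curveTimes(crv), crv@times)
  expect_identical(curveFraction(crv), crv@fraction)
  expect_identical(noiseSigma(crv), crv@sigma)
  map <- genTAMap(crv, noise = noiseModel(0, 0))
  expect_identical(wavelengths(map), map@wavelengths)
  expect_identical(delays(map), map@delays)
  expect_identical(deltaA(map), map@deltaA)
  res <- svdDecompose(map)
  expect_identical(singularValues(res), res@d)
  expect_identical(spectralComponents(res), res@u)
  expect_identical(temporalAmplitudes(res), res@v)
  expect_identical(rankSelected(res), res@rankSelected)
})

test_that("show methods print a summary", {
  expect_output(show(CycleParameters(4.3, 8.9, 100)), "apparent pKa")
  expect_output(show(np7Rates("wt", 5.5)), "k_m1")
  t <- logTimeGrid(1e-12, 1e-9, 4)
  expect_output(show(ProgressCurve(t, exp(-t / 1e-10))), "progress curve")
  map <- genTAMap(ProgressCurve(t, exp(-t / 1e-10)), noise = noiseModel(0, 0))
  expect_output(show(map), "wavelengths x")
  expect_output(show(svdDecompose(map)), "significant")
})
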