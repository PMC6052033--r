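cleanMap <- function(points = 12) {
  t <- logTimeGrid(1e-13, 1e-3, points)
  kin <- simulateRebinding(np7Rates("wt", 5.5), condition = Condition(coAtm = 1),
                           times = t)
  genTAMap(kin, noise = noiseModel(0, 0))
}

test_that("a noise-free rank-1 map is detected as rank 1 with exact factors", {
  map <- cleanMap()
  res <- svdDecompose(map)
  expect_equal(rankSelected(res), 1L)
  expect_lt(singularValues(res)[2] / singularValues(res)[1], 1e-10)
  ## temporal amplitude reproduces the kinetics up to normalization
  kin <- simulateRebinding(np7Rates("wt", 5.5), condition = Condition(coAtm = 1),
                           times = delays(map))
  v1 <- temporalAmplitudes(res)[, 1]
  expect_gt(stats::cor(v1, kin@fraction), 1 - 1e-10)
  ## sign anchored positive at 436 nm
  iref <- which.min(abs(wavelengths(map) - 436))
  expect_gt(spectralComponents(res)[iref, 1], 0)
  ## componentKinetics reproduces the 436-nm slice of a rank-1 map
  ck <- componentKinetics(res, 1, map)
  expect_equal(ck$trace, unname(deltaA(map)[iref, ]), tolerance = 1e-10)
})

test_that("rank selection is robust to noise and rejects pure noise", {
  t <- logTimeGrid(1e-13, 1e-3, 12)
  kin <- simulateRebinding(np7Rates("wt", 5.5), condition = Condition(coAtm = 1),
                           times = t)
  noisy <- genTAMap(kin, noise = noiseModel(0, 0.005, seed = 5))
  expect_equal(rankSelected(svdDecompose(noisy)), 1L)
  pure <- withr::with_seed(8,
    TAMap(seq(380, 470, 0.5), t,
          matrix(rnorm(181 * length(t)), 181)))
  expect_equal(rankSelected(svdDecompose(pure)), 0L)
})

test_that("componentKinetics refuses indices beyond the selected rank", {
  map <- cleanMap()
  res <- svdDecompose(map)
  expect_error(componentKinetics(res, 2, map), "exceeds the selected rank")
})

test_that("isosbestic points are found at the constructed crossings", {
  map <- cleanMap()
  iso <- findIsosbestic(map)
  expect_equal(length(iso), 2L)
  expect_lt(abs(iso[1] - 402), 0.05)
  expect_lt(abs(iso[2] - 426), 0.05)
})

test_that("isosbestic detection tolerates noise and rejects sign-constant maps", {
  t <- logTimeGrid(1e-13, 1e-3, 12)
  kin <- simulateRebinding(np7Rates("wt", 5.5), condition = Condition(coAtm = 1),
                           times = t)
  noisy <- genTAMap(kin, noise = noiseModel(0, 0.005, seed = 7))
  iso <- findIsosbestic(noisy)
  expect_equal(length(iso), 2L)
  expect_lt(abs(iso[1] - 402), 0.5)
  expect_lt(abs(iso[2] - 426), 0.5)
  pos <- cleanMap()
  pos@deltaA <- abs(pos@deltaA) + 1e-3
  expect_length(findIsosbestic(pos), 0L)
})

test_that("svdDecompose and findIsosbestic validate their inputs", {
  map <- cleanMap()
  bad <- map
  bad@deltaA[1, 1] <- NA_real_
  expect_error(svdDecompose(bad))
  two <- TAMap(wavelengths(map), delays(map)[1:2], deltaA(map)[, 1:2])
  expect_error(findIsosbestic(two), "at least 3 delays")
})
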