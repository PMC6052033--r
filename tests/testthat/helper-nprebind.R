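## Shared generators for the property suites. Ranges cover the physically
## sensible scales of the scheme (geminate rates 1e8-1e11 s^-1, docking-site
## release 1e2-1e5 s^-1, bimolecular entry 1e7-1e9 M^-1 s^-1).

randomCycle <- function() {
  CycleParameters(pkaOpen = stats::runif(1, 2, 12),
                  pkaClosed = stats::runif(1, 2, 12),
                  kD = 10^stats::runif(1, -3, 4))
}

randomRates <- function() {
  MicroRates(k_m1 = 10^stats::runif(1, 9, 11),
             k_2  = 10^stats::runif(1, 8, 10),
             k_m2 = 10^stats::runif(1, 7, 9),
             k_3  = 10^stats::runif(1, 2, 4),
             k_m3 = 10^stats::runif(1, 2, 4),
             k_c  = 10^stats::runif(1, 8, 10),
             k_mc = 10^stats::runif(1, 8, 10),
             k_d  = 10^stats::runif(1, 7, 9),
             k_md = 10^stats::runif(1, 3, 5),
             k_e  = 10^stats::runif(1, 9, 11),
             k_me = 10^stats::runif(1, 9, 11))
}

## drop the fully rebound tail where the signal is pinned at ~0 and the
## declared noise no longer describes the data
trimCurve <- function(curve, floor = 2e-3) {
  keep <- curve@fraction > floor
  ProgressCurve(curve@times[keep], curve@fraction[keep],
                if (length(curve@sigma)) curve@sigma[keep] else numeric(0))
}

allFixtures <- function() {
  list(wt55 = np7Rates("wt", 5.5), wt75 = np7Rates("wt", 7.5),
       ev55 = np7Rates("E27V", 5.5), ev75 = np7Rates("E27V", 7.5),
       eq55 = np7Rates("E27Q", 5.5), eq75 = np7Rates("E27Q", 7.5))
}

lag1 <- function(x) {
  x <- x - mean(x)
  sum(x[-1] * x[-length(x)]) / sum(x^2)
}
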