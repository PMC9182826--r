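# compact scenario constructors for tests

quickScenario <- function(seed, n = 2000, m = 10, h0 = 0.01, theta = log(1.2),
                          confExp = 0.5, confHr = 0.5, r2 = 0.05,
                          missing = 0, prevalent = 0, ...) {
  MrScenario(nSamples = n, nSnps = m, baselineHazard = h0,
             causalLogHr = theta, confounderEffectExposure = confExp,
             confounderLogHr = confHr, instrumentR2 = r2,
             missingRate = missing, prevalentRate = prevalent,
             seed = seed, ...)
}

# simulate and return the pieces most tests need
quickSim <- function(seed, ...) {
  sim <- simulateCohort(quickScenario(seed, ...))
  sim$cohort <- cohortData(sim$panel)
  sim
}

# minimal cohort covariate frame for direct engine calls
noCovars <- function(n) data.frame(row.names = seq_len(n))
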