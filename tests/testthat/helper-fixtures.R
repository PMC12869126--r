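# shared fixtures: tiny configs and sessions built in code

tinyConfig <- function(nSamples = 400, seed = 11, ...) {
  syntheticConfig(nSamples = nSamples, seed = seed, ...)
}

quietSession <- function(config, group = "control", id = "s1",
                         seed = config$seed) {
  suppressMessages(generateSession(config, group, id, seed = seed))
}

quietCohort <- function(config, nPerGroup = 2) {
  suppressMessages(generateCohort(config, nPerGroup = nPerGroup))
}

# independent percentile oracle: explicit linear interpolation at (n-1)p
oraclePercentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

oracleWinsorize <- function(x) {
  q1 <- oraclePercentile(x, 0.25)
  q3 <- oraclePercentile(x, 0.75)
  lf <- q1 - 1.5 * (q3 - q1)
  uf <- q3 + 1.5 * (q3 - q1)
  pmin(pmax(x, lf), uf)
}
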