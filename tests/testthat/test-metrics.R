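constantSession <- function(bands = c(2, 5, 3), oxy = 6, red = 4,
                            crbc = 1.5, n = 20, group = "control") {
  tot <- sum(bands)
  hbT <- oxy + red
  RecordingSession("const", group, list(
    CRBC = rep(crbc, n), SO2 = rep(100 * oxy / hbT, n),
    HB_TOTAL = rep(hbT, n), HB_OXY = rep(oxy, n), HB_RED = rep(red, n),
    BP_LOW = rep(bands[1], n), BP_MID = rep(bands[2], n),
    BP_HIGH = rep(bands[3], n), BP_TOTAL = rep(tot, n),
    BP_CONV = rep(100, n)))
}

test_that("speed-band shares are band-mean proportions summing to 100", {
  sb <- summarizeSpeedBands(constantSession(c(2, 5, 3)))
  expect_equal(c(sb$relLow, sb$relMid, sb$relHigh), c(20, 50, 30))
  expect_equal(sb$meanTotal, 10)

  sb0 <- summarizeSpeedBands(constantSession(c(0, 5, 5)))
  expect_equal(c(sb0$relLow, sb0$relMid, sb0$relHigh), c(0, 50, 50))

  allZero <- summarizeSpeedBands(constantSession(c(0, 0, 0)))
  expect_false(allZero$defined)
  expect_true(is.na(allZero$relLow))
})

test_that("oxygenation shares and ratio", {
  ox <- oxygenSummary(constantSession(oxy = 6, red = 4))
  expect_equal(c(ox$relOxy, ox$relRed), c(60, 40))
  expect_equal(ox$oxyRedRatio, 1.5)
  expect_equal(oxygenSummary(constantSession(oxy = 5, red = 5))$oxyRedRatio, 1)
  zero <- oxygenSummary(constantSession(oxy = 0, red = 0))
  expect_false(zero$defined)
})

test_that("share invariant: bands and hemoglobin shares sum to 100", {
  cfg <- tinyConfig(nSamples = 300, seed = 13)
  for (g in groupLabels()) {
    s <- quietSession(cfg, g, g)
    sb <- summarizeSpeedBands(s)
    expect_equal(sb$relLow + sb$relMid + sb$relHigh, 100, tolerance = 1e-6)
    ox <- oxygenSummary(s)
    expect_equal(ox$relOxy + ox$relRed, 100, tolerance = 1e-6)
  }
})

test_that("velocity and resistance index formulas", {
  expect_equal(computeMvel(10, 2), 5)
  expect_equal(computeMvel(0, 3), 0)
  expect_equal(computeMvel(20, 4), computeMvel(10, 2))  # joint homogeneity
  expect_error(computeMvel(1, 0), "positive")

  expect_equal(computeImr(10, 5, 10, 0.15), 10 / (5 * 10 * 0.15))
  expect_equal(computeImr(10, 5, 10, 0.15), 1.3333, tolerance = 1e-4)
  # doubling mbp with mvel recomputed from the same CRBC leaves IMR fixed
  expect_equal(computeImr(2 * 10, 2 * 5, 10, 0.15),
               computeImr(10, 5, 10, 0.15))
  expect_error(computeImr(10, 5, 0, 0.15), "positive")
  # micrometre input is converted: same S either way
  expect_equal(computeImr(10, 5, 10, 150, sUnit = "um"),
               computeImr(10, 5, 10, 0.15))
})

test_that("oscillation counting matches the closed-form cycle count", {
  tt <- seq(0, 60 - 0.05, by = 0.05)  # 20 Hz, 60 s
  clean <- sin(2 * pi * 0.5 * tt)
  expect_lt(abs(estimateMfre(clean, 0.05) - 30), 1)

  expect_equal(estimateMfre(rep(3, 100), 0.05), 0)
  expect_error(estimateMfre(c(1, 2), 0.05), "insufficient")

  set.seed(19)
  noisy <- clean + rnorm(length(tt), sd = 0.05)
  expect_lt(abs(estimateMfre(noisy, 0.05) - 30) / 30, 0.05)
})

test_that("oscillation count agrees with the spectral peak on sinusoids", {
  for (fHz in c(0.2, 0.5, 1.0)) {
    tt <- seq(0, 120 - 0.05, by = 0.05)
    x <- sin(2 * pi * fHz * tt)
    # independent oracle: dominant periodogram frequency
    sp <- spec.pgram(ts(x, frequency = 20), plot = FALSE, taper = 0)
    peak <- sp$freq[which.max(sp$spec)] * 60
    expect_lt(abs(estimateMfre(x, 0.05) - peak) / peak, 0.05)
  }
})

test_that("noiseless session indices match hand-chained formulas", {
  cfg <- syntheticConfig(
    nSamples = 1200, seed = 5, samplingInterval = 0.1,
    noiseSds = c(crbc = 0, hbOxy = 0, hbRed = 0, bpLow = 0, bpMid = 0,
                 bpHigh = 0, bpConv = 0),
    vasomotionAmplitude = 0.1)
  s <- quietSession(cfg, "control", "clean")
  idx <- sessionIndices(s)
  mbp <- mean(channelValues(s, "BP_TOTAL"))
  mvel <- mbp / mean(channelValues(s, "CRBC"))
  expect_equal(idx$mbp, mbp)
  expect_equal(idx$mvel, mvel)
  expect_equal(idx$mfre, 15)  # control vasomotion, 120 s of clean signal
  expect_equal(idx$imr, mbp / (mvel * 15 * 0.15))

  # S given in micrometres differs by exactly 1000x from the same S in mm
  um <- sessionIndices(s, sConstant = 150, sUnit = "um")
  mm <- sessionIndices(s, sConstant = 150, sUnit = "mm")
  expect_equal(mm$imr * 1000, um$imr)
})

test_that("cohort metric table carries one row per subject", {
  cfg <- tinyConfig(nSamples = 200)
  coh <- quietCohort(cfg, nPerGroup = 2)
  tab <- cohortMetrics(coh)
  expect_identical(nrow(tab), 12L)
  expect_true(all(c("relHigh", "meanSo2", "mfre", "imr") %in% names(tab)))
  expect_false(anyDuplicated(tab$subjectId) > 0)
})
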