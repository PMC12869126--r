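test_that("generation is deterministic in (config, group, id, seed)", {
  cfg <- tinyConfig()
  a <- quietSession(cfg, "t2dm", "m1", seed = 99)
  b <- quietSession(cfg, "t2dm", "m1", seed = 99)
  expect_identical(channelMatrix(a), channelMatrix(b))
  c <- quietSession(cfg, "t2dm", "m1", seed = 100)
  expect_false(identical(channelMatrix(a), channelMatrix(c)))
})

test_that("zero noise and zero vasomotion give constant group baselines", {
  cfg <- syntheticConfig(
    nSamples = 50, seed = 5,
    noiseSds = c(crbc = 0, hbOxy = 0, hbRed = 0, bpLow = 0, bpMid = 0,
                 bpHigh = 0, bpConv = 0),
    vasomotionAmplitude = 0)
  s <- quietSession(cfg, "t2dm", "flat")
  ch <- channelMatrix(s)
  expect_true(all(apply(ch, 1, function(v) diff(range(v)) == 0)))
  bl <- cfg$baselines
  prof <- cfg$groupProfiles$t2dm
  expect_equal(unname(ch["BP_HIGH", 1]), bl[["bpHigh"]] * 0.6)
  expect_equal(unname(ch["BP_LOW", 1]), bl[["bpLow"]] * 0.9)
  expect_equal(unname(ch["CRBC", 1]), bl[["crbc"]] * 0.85)
  expect_equal(unname(ch["SO2", 1]), bl[["so2"]] + prof$so2Shift)
  expect_equal(unname(ch["BP_TOTAL", 1]),
               unname(ch["BP_LOW", 1] + ch["BP_MID", 1] + ch["BP_HIGH", 1]))
})

test_that("latent driver hits the target correlation (closed-form weight)", {
  # oracle: with unit-variance components and mixing weight w, the induced
  # correlation is w / sqrt(w^2 + 1); the generator inverts this, so the
  # sample r must recover the configured target
  for (target in c(0.3, 0.5, 0.8)) {
    cfg <- syntheticConfig(nSamples = 2000, seed = 21,
                           targetCorrelation = target)
    s <- quietSession(cfg, "control", "r1")
    r <- cor(channelValues(s, "HB_OXY"), channelValues(s, "BP_LOW"))
    expect_lt(abs(r - target), 0.1)
  }
})

test_that("cohorts have the right size, unique ids, and are reproducible", {
  cfg <- tinyConfig(nSamples = 60)
  coh <- quietCohort(cfg, nPerGroup = 9)
  expect_length(coh, 54)
  groups <- vapply(coh, groupLabel, character(1))
  expect_equal(unname(table(groups)[groupLabels()]),
               rep(9L, 6), ignore_attr = TRUE)
  ids <- vapply(coh, subjectId, character(1))
  expect_false(anyDuplicated(ids) > 0)

  one <- quietCohort(cfg, nPerGroup = 1)
  expect_setequal(vapply(one, groupLabel, character(1)), groupLabels())

  coh2 <- quietCohort(cfg, nPerGroup = 9)
  expect_identical(lapply(coh, channelMatrix), lapply(coh2, channelMatrix))
})

test_that("sample means converge to group-adjusted baselines (3 SE)", {
  cfg <- tinyConfig(nSamples = 5000, seed = 31)
  for (g in c("control", "t2dm")) {
    s <- quietSession(cfg, g, paste0(g, "_m"))
    prof <- cfg$groupProfiles[[g]]
    bl <- cfg$baselines
    expected <- c(
      CRBC = bl[["crbc"]] * prof$crbcMultiplier,
      BP_LOW = bl[["bpLow"]] * prof$perfusionMultipliers[["low"]],
      BP_MID = bl[["bpMid"]] * prof$perfusionMultipliers[["mid"]],
      BP_HIGH = bl[["bpHigh"]] * prof$perfusionMultipliers[["high"]])
    for (k in names(expected)) {
      v <- channelValues(s, k)
      se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - expected[[k]]), 3 * se)
    }
  }
})

test_that("artifact injection displaces exactly floor(rate * n) samples", {
  cfg <- tinyConfig(nSamples = 1000, seed = 41)
  s <- quietSession(cfg)

  none <- injectArtifacts(s, rate = 0, seed = 1)
  expect_identical(channelMatrix(none$session), channelMatrix(s))
  expect_length(none$injected$BP_TOTAL, 0)

  inj <- injectArtifacts(s, rate = 0.05, magnitudeSd = 8, seed = 2)
  expect_length(inj$injected$BP_TOTAL, 50)
  changed <- which(channelMatrix(inj$session)["BP_TOTAL", ] !=
                     channelMatrix(s)["BP_TOTAL", ])
  expect_identical(changed, inj$injected$BP_TOTAL)
  # conservation deliberately broken at injected indices
  rep <- validateSession(inj$session)
  expect_true(all(inj$injected$BP_TOTAL %in%
                    rep$index[rep$rule == "bp_conservation"]))

  expect_error(injectArtifacts(s, rate = 1.2), "rate")
})

test_that("vasomotion frequency is recoverable when noise is small", {
  cfg <- syntheticConfig(
    nSamples = 1200, seed = 51,
    noiseSds = c(crbc = 0.08, hbOxy = 2, hbRed = 1, bpLow = 0.004,
                 bpMid = 0.004, bpHigh = 0.004, bpConv = 6),
    vasomotionAmplitude = 0.15)
  for (g in c("control", "t2dm")) {
    s <- quietSession(cfg, g, g)
    truth <- cfg$groupProfiles[[g]]$vasomotionFreq
    expect_lt(abs(estimateMfre(s) - truth) / truth, 0.05)
  }
})
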