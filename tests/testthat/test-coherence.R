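test_that("equal-width bins and the boundary closure rule", {
  edges <- makeBins(c(0, 100))
  expect_equal(edges, seq(0, 100, by = 10))
  expect_length(edges, 11)  # 10 intervals
  expect_error(makeBins(rep(5, 4)), "degenerate")
  expect_equal(makeBins(rep(5, 4), rangeOverride = c(0, 10)),
               seq(0, 10, by = 1))

  # max value lands in the LAST interval, not an 11th one
  m <- jointHistogram(c(100), c(50), makeBins(c(0, 100)), makeBins(c(0, 100)))
  expect_identical(which(coherenceCounts(m) > 0, arr.ind = TRUE)[1, 1],
                   c(row = 10L))
})

test_that("joint histogram counts and conservation", {
  be <- makeBins(c(0, 10)); se <- makeBins(c(0, 10))
  m <- jointHistogram(c(1.1, 1.2, 1.3), c(2.1, 2.2, 2.3), be, se,
                      group = "control")
  cnt <- coherenceCounts(m)
  expect_identical(sum(cnt), 3L)
  expect_identical(cnt[2, 3], 3L)  # all three pairs share one cell
  expect_identical(nPairs(m), 3L)

  expect_error(jointHistogram(1:3, 1:4, be, se), "equal length")

  set.seed(37)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    m <- jointHistogram(runif(n, 0, 10), runif(n, 0, 10), be, se)
    expect_identical(sum(coherenceCounts(m)), n)
  }
})

test_that("uniform pairs fill cells at the multinomial expectation", {
  set.seed(43)
  n <- 10000
  m <- jointHistogram(runif(n, 0, 1), runif(n, 0, 1),
                      makeBins(c(0, 1)), makeBins(c(0, 1)))
  expectCell <- n / 100
  sdCell <- sqrt(n * (1 / 100) * (99 / 100))
  expect_true(all(abs(coherenceCounts(m) - expectCell) <= 4 * sdCell))
})

test_that("chord payload normalizes marginals and joints", {
  be <- makeBins(c(0, 2), k = 2); se <- makeBins(c(0, 2), k = 2)
  # counts [[2,0],[1,1]] via explicit points
  m <- jointHistogram(c(0.5, 0.5, 1.5, 1.5), c(0.5, 0.5, 0.5, 1.5), be, se)
  expect_identical(coherenceCounts(m), matrix(c(2L, 1L, 0L, 1L), 2))
  pl <- chordPayload(m)
  expect_equal(pl$chords$width, c(0.5, 0.25, 0.25))
  bpArcs <- pl$arcs[pl$arcs$side == "BP", ]
  so2Arcs <- pl$arcs[pl$arcs$side == "SO2", ]
  expect_equal(bpArcs$width, c(0.5, 0.5))
  expect_equal(so2Arcs$width, c(0.75, 0.25))
  expect_equal(sum(bpArcs$width), 1)
  expect_equal(sum(so2Arcs$width), 1)
  expect_equal(sum(pl$chords$width), 1)

  # single-cell matrix: one chord of width 1, one full arc per side
  m1 <- jointHistogram(rep(0.5, 7), rep(0.5, 7), be, se)
  pl1 <- chordPayload(m1)
  expect_identical(nrow(pl1$chords), 1L)
  expect_equal(pl1$chords$width, 1)

  # zero-count chords are omitted
  expect_identical(nrow(pl$chords), 3L)

  flt <- filterChords(pl, bpIntervals = 2)
  expect_true(all(flt$chords$bpInterval == 2))
})

test_that("payload is invariant to jointly permuting time indices", {
  set.seed(47)
  bp <- runif(200, 0, 5); so2 <- runif(200, 40, 90)
  be <- makeBins(bp); se <- makeBins(so2)
  p1 <- chordPayload(jointHistogram(bp, so2, be, se))
  perm <- sample(200)
  p2 <- chordPayload(jointHistogram(bp[perm], so2[perm], be, se))
  expect_identical(p1, p2)
})

test_that("correlation report: self-correlation, relevance rule, ordering", {
  cfg <- tinyConfig(nSamples = 500, seed = 53)
  sessions <- lapply(1:3, function(i)
    quietSession(cfg, "control", paste0("c", i), seed = i))
  rep <- correlateChannels(sessions, group = "control")
  expect_equal(unname(diag(rep$r)), rep(1, 10))
  expect_false(any(diag(rep$relevant)))
  expect_true(isSymmetric(rep$r))
  expect_identical(rep$n, 1500L)
  expect_setequal(rep$dendrogramOrder, channelKinds())

  # relevance is a pure function of (r, p, thresholds)
  expect_identical(rep$relevant,
                   !is.na(rep$r) & rep$p < 0.05 & abs(rep$r) > 0.4 &
                     row(rep$r) != col(rep$r))

  # r = 0.45 at n = 200 clears both thresholds
  r <- 0.45; n <- 200
  p <- 2 * pt(abs(r * sqrt((n - 2) / (1 - r^2))), n - 2, lower.tail = FALSE)
  expect_lt(p, 0.05)

  # the engineered HB_OXY ~ BP_LOW coupling is recovered and flagged
  expect_lt(abs(rep$r["HB_OXY", "BP_LOW"] - 0.5), 0.1)
  expect_true(rep$relevant["HB_OXY", "BP_LOW"])
})

test_that("constant channels are flagged, not fatal", {
  s <- RecordingSession("c", "control", list(
    CRBC = rep(1, 50), BP_LOW = rnorm(50, 10), BP_MID = rnorm(50, 10)))
  rep <- correlateChannels(list(s))
  expect_true(is.na(rep$r["CRBC", "BP_LOW"]))
  expect_false(rep$relevant["CRBC", "BP_LOW"])
  expect_false(is.na(rep$r["BP_LOW", "BP_MID"]))
})

test_that("pooled ranges make group matrices comparable", {
  cfg <- tinyConfig(nSamples = 300, seed = 59)
  coh <- quietCohort(cfg, nPerGroup = 2)
  mats <- groupCoherence(coh, range = "pooled")
  edges <- lapply(mats, function(m) coherenceEdges(m))
  for (g in names(edges)[-1]) expect_identical(edges[[g]], edges[[1]])
  perGroup <- groupCoherence(coh, range = "per-group")
  expect_false(identical(coherenceEdges(perGroup[[1]]),
                         coherenceEdges(perGroup[[2]])))
})
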