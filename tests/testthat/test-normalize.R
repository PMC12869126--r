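test_that("worked examples of all four transforms", {
  z <- normalizeZscore(c(1, 2, 3))
  expect_equal(z$transformed, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(z$parameters$sd, sqrt(2 / 3))  # population sd, divisor n

  expect_equal(normalizeMinmax(c(2, 4, 6))$transformed, c(0, 0.5, 1))
  expect_equal(normalizeMinmax(c(-3, 1))$transformed, c(0, 1))
  expect_equal(normalizeL2(c(3, 4))$transformed, c(0.6, 0.8))
  expect_equal(normalizeL2(c(0, 0, 5))$transformed, c(0, 0, 1))
  expect_equal(normalizeMedian(c(2, 4, 8))$transformed, c(0.5, 1, 2))
  expect_equal(normalizeMedian(c(1, 3))$transformed, c(0.5, 1.5))  # even n
})

test_that("degenerate inputs raise typed conditions", {
  expect_error(normalizeZscore(c(7, 7, 7)), class = "microcohere_degenerate")
  expect_error(normalizeMinmax(c(7, 7, 7)), class = "microcohere_degenerate")
  expect_error(normalizeL2(c(0, 0)), class = "microcohere_degenerate")
  expect_error(normalizeMedian(c(-1, 0, 1)), class = "microcohere_degenerate")
})

test_that("output contracts hold on random inputs", {
  set.seed(97)
  for (i in 1:50) {
    x <- rnorm(sample(5:200, 1), mean = runif(1, -50, 50),
               sd = runif(1, 0.1, 30))
    expect_lt(abs(mean(normalizeZscore(x)$transformed)), 1e-9)
    expect_lt(abs(sqrt(mean(normalizeZscore(x)$transformed^2)) - 1), 1e-9)
    mm <- normalizeMinmax(x)$transformed
    expect_identical(min(mm), 0)
    expect_identical(max(mm), 1)
    expect_lt(abs(sqrt(sum(normalizeL2(x)$transformed^2)) - 1), 1e-9)
    if (median(x) != 0)
      expect_lt(abs(median(normalizeMedian(x)$transformed) - 1), 1e-9)
  }
})

test_that("permutation, affine and scale invariances", {
  set.seed(101)
  x <- rnorm(40, 10, 3)
  perm <- sample(40)
  for (m in c("zscore", "minmax", "l2", "median")) {
    expect_equal(normalizeValues(x[perm], m)$transformed,
                 normalizeValues(x, m)$transformed[perm])
  }
  # zscore/minmax invariant under x -> a x + b (a > 0)
  y <- 3.7 * x + 12
  expect_equal(normalizeZscore(y)$transformed,
               normalizeZscore(x)$transformed)
  expect_equal(normalizeMinmax(y)$transformed,
               normalizeMinmax(x)$transformed)
  # l2/median invariant under pure scaling but NOT under shifts
  expect_equal(normalizeL2(3.7 * x)$transformed, normalizeL2(x)$transformed)
  expect_equal(normalizeMedian(3.7 * x)$transformed,
               normalizeMedian(x)$transformed)
  expect_false(isTRUE(all.equal(normalizeL2(x + 12)$transformed,
                                normalizeL2(x)$transformed)))
  expect_false(isTRUE(all.equal(normalizeMedian(x + 12)$transformed,
                                normalizeMedian(x)$transformed)))
  # minmax preserves sort order
  expect_identical(order(normalizeMinmax(x)$transformed), order(x))
})

test_that("method comparison collapses scales and recommends min-max", {
  small <- runif(50)            # 0-1 scale
  big <- runif(50) * 100        # 0-100 scale
  cmp <- compareMethods(list(small = small, big = big))
  mm <- cmp$summary[cmp$summary$method == "minmax", ]
  expect_equal(mm$whiskerMin, c(0, 0))
  expect_equal(mm$whiskerMax, c(1, 1))
  expect_identical(cmp$recommendedMethod, "minmax")

  # a constant channel knocks out zscore/minmax but not the recommendation
  # logic's error handling; median stays applicable iff nonzero
  cmp2 <- compareMethods(list(a = rnorm(20), flat = rep(5, 20)))
  s2 <- cmp2$summary
  expect_false(s2$applicable[s2$method == "zscore" & s2$channel == "flat"])
  expect_false(s2$applicable[s2$method == "minmax" & s2$channel == "flat"])
  expect_true(s2$applicable[s2$method == "median" & s2$channel == "flat"])
  expect_true(is.na(cmp2$recommendedMethod))
})

test_that("comparison accepts sessions directly", {
  cfg <- tinyConfig(nSamples = 120)
  cmp <- compareMethods(quietSession(cfg))
  expect_identical(cmp$recommendedMethod, "minmax")
  expect_identical(nrow(cmp$summary), 40L)  # 4 methods x 10 channels
})
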