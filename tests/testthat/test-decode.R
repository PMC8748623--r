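test_that("pseudo-populations are balanced, bounded and reproducible", {
  set.seed(51)
  pool <- syntheticPool(30, 10, 2, peripheralLocations())
  cfg <- decodeConfig("location8", nUnits = 30, folds = 5, repeats = 3,
                      resamples = 4, nShuffles = 20)
  pp <- withSeed(1, buildPseudopopulation(pool, cfg))
  expect_equal(dim(pp$tensor), c(30, 80, 2))
  expect_true(all(table(pp$labels) == 10))
  pp2 <- withSeed(1, buildPseudopopulation(pool, cfg))
  expect_identical(pp, pp2)
  acc <- decodeTimecourse(pool, cfg, seed = 2)
  expect_equal(dim(acc), c(2, cfg$repeats * cfg$resamples))
  expect_true(all(acc >= 0 & acc <= 1))
  expect_identical(acc, decodeTimecourse(pool, cfg, seed = 2))
})

test_that("perfectly separable tuning is decoded near ceiling", {
  set.seed(52)
  conds <- peripheralLocations()
  # noiseless, fully distinct condition patterns
  units <- lapply(1:25, function(u) {
    pat <- stats::runif(8, 1, 10)
    byCond <- lapply(seq_along(conds), function(ci)
      matrix(pat[ci], 8, 2))
    names(byCond) <- as.character(conds)
    byCond
  })
  pool <- list(units = units, binCenters = 1:2, conditions = conds)
  cfg <- decodeConfig("location8", nUnits = 25, folds = 4, repeats = 2,
                      resamples = 3, minTrialsPerCondition = 8)
  acc <- decodeTimecourse(pool, cfg, seed = 1)
  expect_gte(mean(acc), 0.99)
})

test_that("shuffled labels decode at chance for both label types", {
  set.seed(53)
  cfg8 <- decodeConfig("location8", nUnits = 60, folds = 10, repeats = 2,
                       resamples = 8, nShuffles = 20)
  pool8 <- syntheticPool(60, 10, 2, peripheralLocations(), sep = 3)
  nul8 <- decodeTimecourse(pool8, cfg8, seed = 4, shuffle = TRUE)
  expect_lt(abs(mean(nul8) - 0.125), 0.02)
  cfg2 <- decodeConfig("match2", nUnits = 60, folds = 10, repeats = 2,
                       resamples = 8, nShuffles = 20)
  pool2 <- syntheticPool(60, 10, 2, c(0L, 1L), sep = 3)
  nul2 <- decodeTimecourse(pool2, cfg2, seed = 4, shuffle = TRUE)
  expect_lt(abs(mean(nul2) - 0.5), 0.03)
})

test_that("training the classifier on test trials breaks the calibration", {
  set.seed(54)
  pool <- syntheticPool(40, 10, 1, c(0L, 1L), noiseSd = 3)
  leaky <- decodeConfig("match2", nUnits = 40, folds = 10, repeats = 2,
                        resamples = 15, nShuffles = 20,
                        leakTestIntoTraining = TRUE)
  nul <- decodeTimecourse(pool, leaky, seed = 5, shuffle = TRUE)
  # test trials inside the centroids drag shuffled accuracy far above chance
  expect_gt(mean(nul), 0.5 + 3 * sd(nul) / sqrt(length(nul)))
  expect_gt(mean(nul), 0.6)
})

test_that("null intervals narrow as trials per condition grow", {
  set.seed(55)
  width <- function(k) {
    pool <- syntheticPool(30, k, 1, c(0L, 1L))
    cfg <- decodeConfig("match2", nUnits = 30, folds = 5, repeats = 2,
                        resamples = 10, nShuffles = 30,
                        minTrialsPerCondition = k)
    nul <- shuffleNull(pool, cfg, seed = 6)
    diff(nul$interval[, 1])
  }
  expect_gt(width(5), width(40))
})

test_that("decoding accuracy is monotone in planted tuning strength", {
  set.seed(56)
  cfg <- decodeConfig("location8", nUnits = 30, folds = 5, repeats = 2,
                      resamples = 5, nShuffles = 20)
  accAt <- function(sep) {
    mean(replicate(8, {
      pool <- syntheticPool(30, 10, 1, peripheralLocations(), sep = sep)
      mean(decodeTimecourse(pool, cfg, seed = sample.int(1e6, 1)))
    }))
  }
  ladder <- c(accAt(0), accAt(2), accAt(6))
  expect_true(all(diff(ladder) > -0.01))
  expect_gt(ladder[3], ladder[1] + 0.2)
})

test_that("significance flags respect the null interval", {
  set.seed(57)
  # actual identical in distribution to the null: flag rate near nominal
  mkRes <- function(actual, null) {
    actual <- pmin(pmax(actual, 0), 1)
    null <- pmin(pmax(null, 0), 1)
    r <- new("DecodingResult", label = "match2",
             binCenters = seq_len(nrow(actual)), accuracy = actual,
             nullAccuracy = null, chance = 0.5,
             flags = logical(nrow(actual)),
             nullInterval = matrix(0, 2, nrow(actual)),
             zP = numeric(nrow(actual)))
    decodeSignificance(r)
  }
  nBins <- 200
  res <- mkRes(matrix(rnorm(nBins * 50, 0.5, 0.05), nBins),
               matrix(rnorm(nBins * 200, 0.5, 0.05), nBins))
  expect_lt(mean(significantBins(res)), 0.15)
  # information in designated bins only
  actual <- matrix(rnorm(nBins * 50, 0.5, 0.05), nBins)
  actual[10:20, ] <- actual[10:20, ] + 0.4
  res2 <- mkRes(actual, matrix(rnorm(nBins * 200, 0.5, 0.05), nBins))
  expect_true(all(significantBins(res2)[10:20]))
  expect_lt(mean(significantBins(res2)[-(10:20)]), 0.15)
})

test_that("match information is planted in the active task only", {
  ds <- mediumExperiment()
  dcfg <- decodeConfig("match2", nUnits = 100, binS = 0.5, stepS = 0.25,
                       folds = 10, repeats = 5, resamples = 10,
                       nShuffles = 20)
  poolP <- binnedConditionRates(ds, "passive", NULL, dcfg)
  resP <- decodeWithNull(poolP, dcfg, seed = 3)
  poolA <- binnedConditionRates(ds, "active", c("II", "III", "IV"), dcfg)
  resA <- decodeWithNull(poolA, dcfg, seed = 3)
  expect_equal(sum(significantBins(resP)), 0)
  expect_gt(sum(significantBins(resA)), 0)
  # the active significant bins sit at/after the second stimulus
  tSig <- resA@binCenters[significantBins(resA)]
  expect_true(all(tSig > 0.2))
})
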