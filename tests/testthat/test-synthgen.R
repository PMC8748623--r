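test_that("identical configuration and seed reproduce the dataset exactly", {
  cfg <- synthConfig(nUnits = 5, nTrialsPerCondition = 2,
                     sessionsPerPhase = 1, nLfpElectrodes = 1, seed = 33)
  ds1 <- generateExperiment(cfg)
  ds2 <- generateExperiment(cfg)
  expect_identical(ds1, ds2)
  dir <- withr::local_tempdir()
  writeDataset(ds1, file.path(dir, "a"))
  writeDataset(ds2, file.path(dir, "b"))
  for (f in list.files(file.path(dir, "a"), recursive = TRUE)) {
    expect_identical(readBin(file.path(dir, "a", f), "raw", 2e7),
                     readBin(file.path(dir, "b", f), "raw", 2e7))
  }
  expect_error(synthConfig(nUnits = 5), "seed")
})

test_that("session structure follows the training curriculum", {
  ds <- smallExperiment()
  phases <- vapply(sessions(ds), sessionPhase, character(1))
  expect_equal(phases, c("pre", "I", "II", "III", "IV"))
  for (s in sessions(ds)) {
    tr <- trials(s)
    if (sessionPhase(s) == "pre") {
      expect_true(all(tr$task == "passive"))
    } else {
      # passive block strictly precedes the active block
      expect_lt(max(which(tr$task == "passive")),
                min(which(tr$task == "active")))
      act <- tr[tr$task == "active", ]
      if (sessionPhase(s) %in% c("I", "II")) {
        expect_true(all(act$cue_location %in% c(3L, 5L)))
      } else {
        expect_setequal(unique(act$cue_location), 0:8)
      }
      if (sessionPhase(s) == "IV") {
        d <- act$t_sample_on - act$t_cue_off
        expect_true(all(d >= 0.25 - 1e-9 & d <= 1.5 + 1e-9))
        expect_gt(length(unique(round(d, 6))), 1)  # variable delays
      }
    }
    pas <- tr[tr$task == "passive", ]
    expect_true(all(abs(pas$t_sample_on - pas$t_cue_off - 1.5) < 1e-9))
    expect_true(all(pas$is_match == (pas$cue_location == pas$sample_location)))
  }
})

test_that("constant-rate spiking recovers the scheduled Poisson mean", {
  sched <- as.list(effectSchedule()[1, ])
  trial <- passiveTrial()
  unit <- list(prefLoc = 0L, baseline = 10, responsive = FALSE,
               matchPref = 1)
  set.seed(11)
  counts <- replicate(600, length(synthesizeUnitSpikes(unit, trial, 1,
                                                       sched)))
  # lambda = 10 spikes/s over a 5 s trial
  se <- sqrt(50 / 600)
  expect_lt(abs(mean(counts) - 50), 3 * se)
  # variance consistent with Poisson (ratio near 1)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("zero tuning amplitude leaves cue and fixation rates equal", {
  sched <- as.list(effectSchedule()[1, ])
  sched$cue_gain <- 1; sched$delay_gain <- 1; sched$ramp_slope <- 0
  trial <- passiveTrial()
  unit <- list(prefLoc = 0L, baseline = 12, responsive = TRUE, matchPref = 1)
  set.seed(12)
  rates <- replicate(500, {
    s <- synthesizeUnitSpikes(unit, trial, 1, sched)
    c(fix = sum(s < 1), cue = sum(s >= 1 & s < 1.5) / 0.5)
  })
  se <- sqrt(12 / 500 + 12 / (500 * 0.5))
  expect_lt(abs(mean(rates["cue", ]) - mean(rates["fix", ])), 3 * se)
})

test_that("large tuning concentration confines cue drive to the preferred location", {
  sched <- as.list(effectSchedule()[1, ])
  sched$cue_gain <- 3; sched$tuning_kappa <- 60
  unit <- list(prefLoc = 0L, baseline = 10, responsive = TRUE, matchPref = 1)
  set.seed(13)
  cueRate <- function(loc) {
    trial <- passiveTrial()
    trial$cue_location <- loc
    trial$sample_location <- loc
    mean(replicate(200, {
      s <- synthesizeUnitSpikes(unit, trial, 1, sched)
      sum(s >= 1 & s < 1.5) / 0.5
    }))
  }
  atPref <- cueRate(0L)
  atOpp <- cueRate(8L)   # diagonal opposite
  expect_gt(atPref, 25)  # ~3x baseline
  expect_lt(abs(atOpp - 10), 1.5)  # back at baseline
})

test_that("shared gains implement distance-decaying correlated variability", {
  grid <- GridGeometry()
  set.seed(14)
  els <- sample(0:63, 36, replace = TRUE)
  # sd = 0: no shared variability, counts independent
  g0 <- drawSharedGains(els, 100, 0, 1, grid)
  expect_true(all(g0 == 1))
  n <- 1500
  counts <- matrix(rpois(n * 36, 8), n, 36)
  rs <- cor(counts)[upper.tri(diag(36))]
  expect_gt(mean(abs(rs) < 3 / sqrt(n)), 0.94)

  # corr_length 1 mm: bin-mean count correlation strictly decreasing
  g <- drawSharedGains(els, 8000, 0.25, 1, grid)
  counts <- matrix(rpois(length(g), 8 * g), nrow(g), ncol(g))
  C <- cor(counts)
  D <- outer(els, els, function(a, b) electrodeDistance(grid, a, b))
  up <- upper.tri(C)
  bins <- cut(D[up], c(-0.01, 0.01, 0.8, 1.6, Inf))
  means <- tapply(C[up], bins, mean)
  expect_true(all(diff(means) < 0))

  # infinite correlation length: same kernel value everywhere
  gInf <- drawSharedGains(els, 4000, 0.25, 1e9, grid)
  cInf <- cor(gInf)
  sameEl <- cInf[up][D[up] < 0.01]
  farEl <- cInf[up][D[up] > 3]
  expect_lt(abs(mean(sameEl) - mean(farEl)), 0.05)
})

test_that("zero responsive fraction yields only false-positive screens", {
  sched <- effectSchedule(overrides = data.frame(
    phase = "pre", task = "passive", responsive_fraction = 0))
  cfg <- synthConfig(nUnits = 50, nTrialsPerCondition = 3,
                     sessionsPerPhase = 2, nLfpElectrodes = 0,
                     schedule = sched, seed = 55)
  ds <- generateExperiment(cfg)
  pre <- Filter(function(s) sessionPhase(s) == "pre", sessions(ds))
  scr <- do.call(rbind, lapply(pre, screenSession, task = "passive"))
  frac <- mean(scr$is_responsive[scr$evaluable])
  # two-epoch OR rule at alpha = 0.05: per-unit false-positive rate is
  # bounded near 1 - 0.95^2 = 0.0975; binomial 99.7% band at n = 100
  expect_gt(frac, 0.0975 - 3 * sqrt(0.0975 * 0.9025 / 100))
  expect_lt(frac, 0.0975 + 3 * sqrt(0.0975 * 0.9025 / 100))
})

test_that("schedule validation enforces the stated ranges", {
  expect_error(effectSchedule(overrides = data.frame(
    phase = "IV", task = "active", ramp_slope = 2)), "phase IV")
  expect_error(effectSchedule(overrides = data.frame(
    phase = "pre", task = "passive", match_info_strength = 0.5)),
    "passive")
  expect_error(effectSchedule(overrides = data.frame(
    phase = "pre", task = "passive", responsive_fraction = 1.2)),
    "responsive_fraction")
  expect_error(effectSchedule(overrides = data.frame(
    phase = "pre", task = "passive", spatial_corr_length_mm = 0)),
    "spatial_corr_length")
})
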