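test_that("epoch rates use half-open windows", {
  tr <- passiveTrial()
  u <- list(unit_id = "u", kind = "MUA", electrode = 0L,
            spikes = list(c(1.0, 1.1, 1.2, 1.3, 1.49)))
  # 5 spikes in the 0.5 s cue epoch [1, 1.5)
  expect_equal(epochRate(u$spikes[[1]], tr, "cue"), 10)
  expect_equal(epochRate(numeric(0), tr, "cue"), 0)
  # a spike exactly at the epoch end belongs to the next epoch
  expect_equal(epochRate(c(1.0, 1.5), tr, "cue"), 2)
  expect_equal(epochRate(c(1.0, 1.5), tr, "delay1"), 1 / 1.5)
})

test_that("the MUA 10% gate applies to the cue epoch and not to single units", {
  # deterministic spike trains: exactly 50 fixation spikes (rate 50) and 27
  # cue spikes (rate 54 = 1.08 x fixation) on every trial
  tr <- locationTrials(12, locs = 5L)
  mkSpikes <- function(nFix, nCue, nDelay = 0) {
    lapply(seq_len(nrow(tr)), function(i)
      c(seq(0, 0.999, length.out = nFix),
        seq(1.0, 1.499, length.out = nCue),
        if (nDelay > 0) seq(1.5, 2.99, length.out = nDelay)))
  }
  u108 <- list(unit_id = "m", kind = "MUA", electrode = 0L,
               spikes = mkSpikes(50, 27))
  res <- screenResponsiveSingleLocation(u108, tr)
  expect_false(res$is_responsive)             # fails the 10% gate
  expect_lt(res$percent_increase, 0.10)
  u108s <- u108; u108s$kind <- "SUA"
  expect_true(screenResponsiveSingleLocation(u108s, tr)$is_responsive)
  # suppression, however strong, never counts as responsive
  uDown <- list(unit_id = "d", kind = "SUA", electrode = 0L,
                spikes = mkSpikes(50, 5))
  expect_false(screenResponsiveSingleLocation(uDown, tr)$is_responsive)
  # a 20% increase passes the MUA gate
  u120 <- list(unit_id = "m2", kind = "MUA", electrode = 0L,
               spikes = mkSpikes(50, 30))
  expect_true(screenResponsiveSingleLocation(u120, tr)$is_responsive)
  # under 5 trials: unevaluable, not unresponsive
  tiny <- tr[1:4, ]
  uTiny <- list(unit_id = "t", kind = "MUA", electrode = 0L,
                spikes = mkSpikes(50, 30)[1:4])
  res <- screenResponsiveSingleLocation(uTiny, tiny)
  expect_false(res$evaluable)
  expect_true(is.na(res$is_responsive))
})

test_that("multi-location screening has power and handles degeneracy", {
  tr <- locationTrials(20)
  sched <- as.list(effectSchedule()[1, ])
  sched$cue_gain <- 2; sched$delay_gain <- 1; sched$tuning_kappa <- 5
  set.seed(21)
  hits <- replicate(60, {
    unit <- list(prefLoc = 0L, baseline = 8, responsive = TRUE,
                 matchPref = 1)
    spikes <- lapply(seq_len(nrow(tr)), function(k)
      synthesizeUnitSpikes(unit, tr[k, ], 1, sched))
    u <- list(unit_id = "u", kind = "MUA", electrode = 0L, spikes = spikes)
    screenResponsiveMultiLocation(u, tr)$is_responsive
  })
  expect_gt(mean(hits), 0.95)
  # identical deterministic rates across locations: not responsive, no error
  uConst <- list(unit_id = "c", kind = "MUA", electrode = 0L,
                 spikes = lapply(seq_len(nrow(tr)), function(i) seq(0, 4.9,
                                                                    by = 0.5)))
  res <- screenResponsiveMultiLocation(uConst, tr)
  expect_true(res$evaluable)
  expect_false(res$is_responsive)
  # too few trials per location: unevaluable
  res2 <- screenResponsiveMultiLocation(uConst, tr[c(1, 21, 41), ])
  expect_false(res2$evaluable)
})

test_that("screening false-positive rate matches the two-epoch OR rule", {
  tr <- locationTrials(8)
  set.seed(22)
  flags <- replicate(400, {
    u <- poissonUnit(tr, 8)
    screenResponsiveMultiLocation(u, tr)$is_responsive
  })
  p0 <- 1 - 0.95^2  # independence bound for the OR of two level-0.05 tests
  expect_lt(abs(mean(flags) - p0), 3 * sqrt(p0 * (1 - p0) / 400))
})

test_that("best location recovers planted preference and breaks ties low", {
  tr <- locationTrials(30)
  sched <- as.list(effectSchedule()[1, ])
  sched$cue_gain <- 3; sched$tuning_kappa <- 8
  set.seed(23)
  hits <- replicate(50, {
    unit <- list(prefLoc = 6L, baseline = 8, responsive = TRUE,
                 matchPref = 1)
    spikes <- lapply(seq_len(nrow(tr)), function(k)
      synthesizeUnitSpikes(unit, tr[k, ], 1, sched))
    u <- list(unit_id = "u", kind = "MUA", electrode = 0L, spikes = spikes)
    bestLocation(u, tr, "cue")
  })
  expect_gt(mean(hits == 6L), 0.98)
  # single location and exact ties
  uConst <- list(unit_id = "c", kind = "MUA", electrode = 0L,
                 spikes = lapply(seq_len(nrow(tr)), function(i) c(1.1, 1.2)))
  expect_equal(bestLocation(uConst, tr[tr$cue_location == 3, ], "cue"), 3L)
  expect_equal(bestLocation(uConst, tr, "cue"), 0L)  # all tied -> lowest
})

test_that("best location is permutation-equivariant", {
  set.seed(24)
  tr <- locationTrials(6)
  u <- poissonUnit(tr, 10)
  b1 <- bestLocation(u, tr, "cue")
  # relabel locations by a fixed permutation of 0..8
  perm <- c(4L, 7L, 0L, 2L, 8L, 1L, 6L, 3L, 5L)
  tr2 <- tr
  tr2$cue_location <- perm[tr$cue_location + 1L]
  tr2$sample_location <- perm[tr$sample_location + 1L]
  expect_equal(bestLocation(u, tr2, "cue"), perm[b1 + 1L])
})

test_that("population PSTH is flat for constant rates and conserves counts", {
  set.seed(25)
  tr <- locationTrials(4)
  units <- lapply(1:15, function(i) poissonUnit(tr, 12, id = paste0("u", i)))
  ps <- populationPsth(units, tr, binS = 0.1)
  expect_lt(abs(mean(ps$mean) - 12), 1.0)
  expect_lt(diff(range(ps$mean)), 6 * max(ps$sem))
  # conservation: sum(rate) * binS equals the mean spike count in the window
  u <- units[[1]]
  loc <- bestLocation(u, tr, "cue")
  rows <- which(tr$cue_location == loc)
  total <- mean(vapply(rows, function(i)
    sum(u$spikes[[i]] >= 0 & u$spikes[[i]] < 5), numeric(1)))
  expect_equal(sum(ps$rateMatrix[1, ]) * 0.1, total, tolerance = 1e-10)
  # baseline subtraction zeroes the fixation bins on average
  psB <- populationPsth(units, tr, binS = 0.1, baselineSubtract = TRUE)
  fixBins <- psB$binCenters < 0
  expect_lt(abs(mean(psB$mean[fixBins])), 3 * mean(psB$sem[fixBins]))
})

test_that("a planted ramp toward the targets is recovered from the PSTH", {
  # active-task trials, fixed 1 s delays so the ramp spans a known window
  n <- 30
  tr <- data.frame(trial_id = seq_len(n), task = "active", phase = "III",
                   cue_location = 5L, sample_location = 5L, is_match = TRUE,
                   correct = TRUE, t_fixation_on = 0, t_cue_on = 1,
                   t_cue_off = 1.5, t_sample_on = 2.5, t_sample_off = 3,
                   t_targets_on = 4, t_end = 4.3)
  sched <- as.list(effectSchedule()[effectSchedule()$phase == "III" &
                                      effectSchedule()$task == "active", ])
  sched$cue_gain <- 1; sched$delay_gain <- 1; sched$ramp_slope <- 3
  sched$match_info_strength <- 0
  set.seed(26)
  units <- lapply(1:60, function(i) {
    unit <- list(prefLoc = 5L, baseline = 8, responsive = TRUE,
                 matchPref = 1)
    list(unit_id = paste0("u", i), kind = "MUA", electrode = 0L,
         spikes = lapply(seq_len(n), function(k)
           synthesizeUnitSpikes(unit, tr[k, ], 1, sched)))
  })
  ps <- populationPsth(units, tr, binS = 0.05)
  inRamp <- ps$binCenters > 0.55 & ps$binCenters < 2.95
  fit <- lm(ps$mean[inRamp] ~ ps$binCenters[inRamp])
  expect_lt(abs(coef(fit)[2] - 3) / 3, 0.10)
})

test_that("mixed post-cue durations require explicit alignment", {
  tr <- locationTrials(2)
  tr$t_end[1] <- 6  # one longer trial
  u <- poissonUnit(tr, 5)
  expect_error(populationPsth(list(u), tr, window = c(-1, 4.5)),
               "common trial extent")
})
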