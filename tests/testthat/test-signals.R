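test_that("DPSS tapers are orthonormal and parameter-checked", {
  tap <- dpssTapers(256, nw = 3, k = 5)
  expect_equal(crossprod(tap), diag(5), tolerance = 1e-10)
  expect_error(dpssTapers(256, nw = 3, k = 6), "2\\*nw")
  expect_error(multitaperPower(rnorm(500), 500, nw = 2, k = 5), "2\\*nw")
})

test_that("injected spikes are detected at threshold and missed below it", {
  fs <- 30000
  set.seed(41)
  n <- fs * 2
  noise <- rnorm(n)
  bf <- signal::butter(3, c(500, 8000) / (fs / 2), type = "pass")
  rmsRef <- sqrt(mean(signal::filtfilt(bf, noise)^2))
  # biphasic spike template ~0.6 ms wide, scaled so the *filtered* waveform
  # reaches the requested multiple of the filtered-noise RMS
  tpl <- c(0, -1, -2.2, -1, 0.8, 1.2, 0.5, 0) / 2.2
  tplPad <- c(rep(0, 300), tpl, rep(0, 300))
  tplPeak <- abs(min(signal::filtfilt(bf, tplPad)))
  insertAt <- round(seq(0.05, 1.95, length.out = 20) * fs)
  mk <- function(amp) {
    x <- noise
    sc <- amp * rmsRef / tplPeak
    for (i in insertAt) x[i:(i + 7)] <- x[i:(i + 7)] + sc * tpl
    x
  }
  ev <- extractMuaEvents(mk(6), fs)
  hits <- vapply(insertAt / fs, function(t0)
    any(abs(ev - t0) < 5e-4 + 8 / fs), logical(1))
  expect_gte(sum(hits), 19)
  # 2 x RMS spikes add essentially nothing beyond the noise-crossing floor
  evLo <- extractMuaEvents(mk(2), fs)
  ev0 <- extractMuaEvents(noise, fs)
  expect_lt(abs(length(evLo) - length(ev0)), 10)
  expect_error(extractMuaEvents(rep(0, 1000), fs), "flat")
})

test_that("noise crossing rate matches the Rice-rate oracle of the filter", {
  fs <- 30000
  set.seed(42)
  x <- rnorm(fs * 10)
  ev <- extractMuaEvents(x, fs)
  # oracle: Rice rate of the zero-phase filtered Gaussian process; the
  # effective power response of filtfilt is |H|^4
  bf <- signal::butter(3, c(500, 8000) / (fs / 2), type = "pass")
  fr <- signal::freqz(bf, n = 8192, Fs = fs)
  S <- Mod(fr$h)^4
  f <- fr$f
  # sampled-sequence crossing rate: fs * P(x1 >= a, x2 < a) for the lag-1
  # correlation of the filtered process, by 1-d numerical integration
  rho <- sum(S * cos(2 * pi * f / fs)) / sum(S)
  a <- -3.5
  integrand <- function(x)
    dnorm(x) * pnorm((a - rho * x) / sqrt(1 - rho^2))
  pCross <- integrate(integrand, a, Inf)$value
  expected <- fs * pCross * 10
  expect_lt(abs(length(ev) - expected) / expected, 0.20)
})

test_that("line power is removed and the passband left flat", {
  fs <- 500
  set.seed(43)
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- rnorm(length(t)) + 2 * sin(2 * pi * 60 * t)
  out <- preprocessLfp(list(e1 = list(x)), fs)
  y <- out$traces$e1[[1]]
  binPower <- function(z, f0) {
    X <- fft(z); f <- (seq_along(z) - 1) * fs / length(z)
    mean(Mod(X[abs(f - f0) < 0.2])^2)
  }
  expect_gt(10 * log10(binPower(x, 60) / binPower(y, 60)), 20)
  # white noise stays flat across the passband (+-3 dB between regions)
  w <- rnorm(fs * 20)
  wy <- preprocessLfp(list(e1 = list(w)), fs)$traces$e1[[1]]
  sp <- multitaperPower(wy, fs, windowS = 2, fMax = 240)
  pw <- colMeans(sp$power)
  reg <- function(lo, hi) mean(pw[sp$freqHz >= lo & sp$freqHz <= hi])
  expect_lt(abs(10 * log10(reg(5, 45) / reg(70, 150))), 3)
  # a 5 Hz component is inside the 0.5-200 Hz passband and retained
  x2 <- sin(2 * pi * 5 * t)
  y2 <- preprocessLfp(list(e1 = list(x2)), fs)$traces$e1[[1]]
  expect_gt(var(y2) / var(x2), 0.8)
})

test_that("variance outliers are flagged on both sides", {
  set.seed(44)
  mk <- function(sd) list(rnorm(6000, 0, sd))
  traces <- c(lapply(1:60, function(i) mk(1)),
              lapply(1:4, function(i) mk(10)))
  names(traces) <- paste0("e", 1:64)
  expect_setequal(flagVarianceOutliers(traces), paste0("e", 61:64))
  # homogeneous channels: nothing flagged
  hom <- lapply(1:30, function(i) mk(1))
  names(hom) <- paste0("e", 1:30)
  expect_length(flagVarianceOutliers(hom), 0)
  # dead channel is a low-side outlier
  dead <- c(lapply(1:20, function(i) mk(1)), list(mk(1e-6)))
  names(dead) <- paste0("e", 1:21)
  expect_equal(flagVarianceOutliers(dead), "e21")
  expect_error(flagVarianceOutliers(hom[1:4]), "at least 8")
  # idempotence: excluding flagged electrodes leaves clean sets unchanged
  expect_length(flagVarianceOutliers(traces[1:60]), 0)
})

test_that("multitaper power localizes tones and preserves variance", {
  fs <- 500
  t <- seq(1 / fs, 4, by = 1 / fs)
  x <- sin(2 * pi * 30 * t)
  sp <- multitaperPower(x, fs)
  pk <- sp$freqHz[which.max(colMeans(sp$power))]
  expect_lt(abs(pk - 30), 3 / 0.5)  # within the taper bandwidth NW/T
  bandPow <- function(sp, lo, hi)
    mean(rowSums(sp$power[, sp$freqHz >= lo & sp$freqHz <= hi, drop = FALSE]))
  expect_gt(bandPow(sp, 20, 45), 10 * bandPow(sp, 8, 14))
  # Parseval: integrated PSD matches the variance of white noise
  set.seed(45)
  w <- rnorm(fs * 10, sd = 1.7)
  spw <- multitaperPower(w, fs, fMax = 250)
  expect_lt(abs(mean(rowSums(spw$power)) * spw$dfHz - var(w)) / var(w), 0.10)
  # agreement with a periodogram-average oracle on band-integrated power
  seg <- matrix(w[1:(250 * 16)], nrow = 250)
  per <- apply(seg, 2, function(s) Mod(fft(s))^2 / (250 * fs))
  fseg <- (0:249) * fs / 250
  oracleBand <- mean(colSums(per[fseg >= 20 & fseg <= 45, ])) * 2 * fs / 250
  mtBand <- bandPow(spw, 20, 45) * spw$dfHz
  expect_lt(abs(mtBand - oracleBand) / oracleBand, 0.15)
})

test_that("band time courses are baseline-anchored and scale exactly", {
  fs <- 500
  set.seed(46)
  # stationary noise: normalized series stays at zero
  w <- rnorm(fs * 5)
  sp <- multitaperPower(w, fs)
  tc <- bandTimecourse(sp, "beta", baselineWindowS = c(0, 0.75), cueOnS = 1)
  expect_lt(abs(mean(tc$value)),
            3 * sd(tc$value) / sqrt(nrow(tc)) + 0.005)
  # planted cue-epoch beta: positive during cue, near zero late in the trial
  trial <- passiveTrial()
  sched <- as.list(effectSchedule()[1, ])
  sched$beta_amp <- 2.5
  vals <- replicate(8, {
    x <- synthesizeLfp(trial, sched, fs)
    spx <- multitaperPower(x, fs)
    tcx <- bandTimecourse(spx, "beta", baselineWindowS = c(0, 0.75),
                          cueOnS = 1)
    c(cue = mean(tcx$value[tcx$time_s >= 1 & tcx$time_s <= 1.5]),
      late = mean(tcx$value[tcx$time_s > 3.5]))
  })
  expect_gt(mean(vals["cue", ]), 5 * abs(mean(vals["late", ])))
  # exact quadratic scaling under a global gain g (power scales by g^2)
  sp2 <- multitaperPower(2 * w, fs)
  tc2 <- bandTimecourse(sp2, "beta", baselineWindowS = c(0, 0.75), cueOnS = 1)
  expect_equal(tc2$value, 4 * tc$value, tolerance = 1e-10)
  # a baseline window that touches the cue is rejected
  expect_error(bandTimecourse(sp, "beta", baselineWindowS = c(0, 1.2),
                              cueOnS = 1), "overlaps")
})

test_that("a planted beta decline across phases is detected session-wise", {
  set.seed(47)
  fs <- 500
  trial <- passiveTrial()
  sch <- effectSchedule()
  pas <- sch[sch$task == "passive", ]
  sessionBeta <- function(schedRow, nTrials = 3) {
    mean(replicate(nTrials, {
      x <- synthesizeLfp(trial, as.list(schedRow), fs)[1:1000]
      sp <- multitaperPower(x, fs)
      tc <- bandTimecourse(sp, "beta", baselineWindowS = c(0, 0.75),
                           cueOnS = 1)
      mean(tc$value[tc$time_s >= 1 & tc$time_s <= 1.5])
    }))
  }
  vals <- c(); ph <- c()
  for (p in 2:5) {
    for (s in 1:8) {
      vals <- c(vals, sessionBeta(pas[p, ]))
      ph <- c(ph, pas$phase[p])
    }
  }
  res <- bandPhaseAnova(vals, ph)
  expect_lt(res$p, 0.01)
  # the planted direction: later phases weaker than phase I
  expect_lt(mean(vals[ph == "IV"]), mean(vals[ph == "I"]))
})
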