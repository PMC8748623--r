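## Synthetic-experiment generator: multi-phase training design with planted,
## configurable plasticity effects that the downstream stages must recover.

#' Planted-effect schedule for the synthetic generator
#'
#' One row per (phase, task) combination giving the generative parameters of
#' that condition. The defaults emulate the qualitative plasticity pattern of
#' a staged match/nonmatch training curriculum: responsive fraction and
#' stimulus-evoked gains grow over training, ramping toward the choice
#' targets is present in phases I--III and disappears when delays become
#' variable in phase IV, shared-gain noise (hence noise correlation) drops in
#' phases III--IV and is higher in the passive than the active task,
#' cue-epoch beta power declines monotonically while alpha rises, and
#' match/nonmatch information is planted in the active task only.
#'
#' Columns: \code{phase}, \code{task}, \code{responsive_fraction} (0--1),
#' \code{baseline_rate} (spikes/s), \code{cue_gain}, \code{delay_gain}
#' (multiplicative, >= 0, applied to responsive units at their preferred
#' location), \code{ramp_slope} (spikes/s per s toward targets-on; 0 in
#' phase IV), \code{shared_noise_sd} (s.d. of the log shared gain),
#' \code{spatial_corr_length_mm}, \code{alpha_amp}, \code{beta_amp},
#' \code{gamma_amp} (cue-epoch band amplitude relative to the fixation
#' baseline), \code{match_info_strength} (0--1, active only) and
#' \code{tuning_kappa} (von Mises concentration over peripheral locations).
#'
#' @param overrides optional data.frame with columns \code{phase},
#'   \code{task} and any parameter columns to override row-wise.
#' @return a data.frame of class \code{EffectSchedule}.
#' @export
effectSchedule <- function(overrides = NULL) {
  sched <- rbind(
    data.frame(
      phase = phaseLevels(), task = "passive",
      responsive_fraction = c(0.20, 0.25, 0.30, 0.35, 0.35),
      baseline_rate = 8,
      cue_gain = c(1.3, 1.4, 1.5, 1.6, 1.5),
      delay_gain = c(1.10, 1.15, 1.15, 1.25, 1.60),
      ramp_slope = 0,
      shared_noise_sd = c(0.22, 0.22, 0.22, 0.16, 0.16),
      spatial_corr_length_mm = 1.0,
      alpha_amp = c(1.00, 1.10, 1.20, 1.35, 1.50),
      beta_amp = c(2.00, 1.80, 1.60, 1.30, 1.10),
      gamma_amp = c(1.20, 1.15, 1.10, 1.05, 1.00),
      match_info_strength = 0,
      tuning_kappa = 1.5,
      stringsAsFactors = FALSE),
    data.frame(
      phase = c("I", "II", "III", "IV"), task = "active",
      responsive_fraction = c(0.30, 0.35, 0.55, 0.45),
      baseline_rate = 9,
      cue_gain = c(1.2, 1.3, 1.9, 1.7),
      delay_gain = c(1.10, 1.20, 1.40, 1.80),
      ramp_slope = c(3, 3, 3, 0),
      shared_noise_sd = c(0.20, 0.20, 0.14, 0.14),
      spatial_corr_length_mm = 1.0,
      alpha_amp = c(1.05, 1.15, 1.30, 1.45),
      beta_amp = c(1.90, 1.60, 1.30, 1.10),
      gamma_amp = c(1.15, 1.10, 1.05, 1.00),
      match_info_strength = c(0.2, 0.5, 0.5, 0.5),
      tuning_kappa = 1.5,
      stringsAsFactors = FALSE))
  if (!is.null(overrides)) {
    failIf(!all(c("phase", "task") %in% names(overrides)),
           "overrides must carry phase and task columns")
    for (i in seq_len(nrow(overrides))) {
      row <- which(sched$phase == overrides$phase[i] &
                     sched$task == overrides$task[i])
      failIf(length(row) != 1L, "no schedule row for phase %s / task %s",
             overrides$phase[i], overrides$task[i])
      for (col in setdiff(names(overrides), c("phase", "task"))) {
        failIf(!col %in% names(sched), "unknown schedule column '%s'", col)
        sched[row, col] <- overrides[i, col]
      }
    }
  }
  validateEffectSchedule(sched)
  class(sched) <- c("EffectSchedule", "data.frame")
  sched
}

validateEffectSchedule <- function(s) {
  failIf(any(s$responsive_fraction < 0 | s$responsive_fraction > 1),
         "responsive_fraction must lie in [0, 1]")
  failIf(any(s$baseline_rate < 0), "baseline_rate must be >= 0")
  failIf(any(s$cue_gain < 0) || any(s$delay_gain < 0),
         "epoch gains must be >= 0")
  failIf(any(s$shared_noise_sd < 0), "shared_noise_sd must be >= 0")
  failIf(any(s$spatial_corr_length_mm <= 0),
         "spatial_corr_length_mm must be > 0")
  failIf(any(s$match_info_strength < 0 | s$match_info_strength > 1),
         "match_info_strength must lie in [0, 1]")
  failIf(any(s$match_info_strength[s$task == "passive"] != 0),
         "match_info_strength must be 0 in the passive task")
  failIf(any(s$tuning_kappa < 0), "tuning_kappa must be >= 0")
  failIf(any(s$ramp_slope[s$phase == "IV"] != 0),
         "ramp_slope must be 0 in phase IV")
  invisible(TRUE)
}

scheduleRow <- function(schedule, phase, task) {
  row <- schedule[schedule$phase == phase & schedule$task == task, ,
                  drop = FALSE]
  failIf(nrow(row) != 1L, "no effect-schedule row for phase %s / task %s",
         phase, task)
  as.list(row)
}

#' Generator configuration
#'
#' @param nUnits units recorded per session.
#' @param nTrialsPerCondition trials per (cue location x match status) cell
#'   in each block.
#' @param sessionsPerPhase sessions (days) per training phase.
#' @param grid a \linkS4class{GridGeometry}.
#' @param timing a \linkS4class{TaskTiming}.
#' @param lfpRateHz LFP sampling rate (>= 500 Hz; must exceed twice the
#'   highest analysis band edge).
#' @param nLfpElectrodes electrodes for which LFP is synthesized.
#' @param schedule an \code{\link{effectSchedule}}.
#' @param seed mandatory master seed; every random stream derives from it.
#' @param suaFraction fraction of units labelled as sorted single units.
#' @param lineHz amplitude-1 line component frequency injected into the LFP
#'   (0 = none); used to exercise line removal.
#' @param activeAccuracy probability an active trial is performed correctly.
#' @return list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nUnits = 24, nTrialsPerCondition = 6,
                        sessionsPerPhase = 3, grid = GridGeometry(),
                        timing = TaskTiming(), lfpRateHz = 500,
                        nLfpElectrodes = 8, schedule = effectSchedule(),
                        seed, suaFraction = 0.3, lineHz = 0,
                        activeAccuracy = 0.85) {
  failIf(missing(seed) || is.null(seed) || is.na(seed),
         "a master seed is mandatory")
  failIf(nUnits < 1 || nTrialsPerCondition < 1 || sessionsPerPhase < 1,
         "counts must be >= 1")
  failIf(lfpRateHz < 500, "lfpRateHz must be >= 500")
  failIf(lfpRateHz < 2 * 70, "lfpRateHz must exceed twice the top band edge")
  validateEffectSchedule(schedule)
  cfg <- list(nUnits = as.integer(nUnits),
              nTrialsPerCondition = as.integer(nTrialsPerCondition),
              sessionsPerPhase = as.integer(sessionsPerPhase),
              grid = grid, timing = timing, lfpRateHz = lfpRateHz,
              nLfpElectrodes = as.integer(nLfpElectrodes),
              schedule = schedule, seed = as.integer(seed),
              suaFraction = suaFraction, lineHz = lineHz,
              activeAccuracy = activeAccuracy)
  class(cfg) <- "SynthConfig"
  cfg
}

## ---------------------------------------------------------------------------
## Trial construction
## ---------------------------------------------------------------------------

## Cue locations available to the active task in each phase: the curriculum
## starts with the horizontal pair (left = 3, right = 5) and opens up to all
## nine grid locations from phase III.
activeCueLocations <- function(phase) {
  if (phase %in% c("I", "II")) c(3L, 5L) else 0:8
}

buildTrialBlock <- function(task, phase, timing, nPerCondition,
                            activeAccuracy, startId) {
  cues <- if (task == "passive") 0:8 else activeCueLocations(phase)
  grid <- expand.grid(cue = cues, match = c(TRUE, FALSE),
                      rep = seq_len(nPerCondition))
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  n <- nrow(grid)
  delay <- if (task == "passive") {
    rep(timing@passiveDelayS, n)
  } else if (phase == "IV") {
    r <- timing@phase4DelayRangeS
    stats::runif(n, r[1], r[2])
  } else {
    rep(timing@activeDelayS[[phase]], n)
  }
  tCueOn <- timing@fixationS
  tCueOff <- tCueOn + timing@cueS
  tSampleOn <- tCueOff + delay
  tSampleOff <- tSampleOn + timing@sampleS
  tAfter <- tSampleOff + delay       # second delay matches the first
  sample <- ifelse(grid$match, grid$cue, diametricLocation(grid$cue))
  data.frame(
    trial_id = startId + seq_len(n) - 1L,
    task = task, phase = phase,
    cue_location = as.integer(grid$cue),
    sample_location = as.integer(sample),
    is_match = grid$match,
    correct = if (task == "passive") rep(TRUE, n) else
      stats::runif(n) < activeAccuracy,
    t_fixation_on = 0,
    t_cue_on = tCueOn, t_cue_off = tCueOff,
    t_sample_on = tSampleOn, t_sample_off = tSampleOff,
    t_targets_on = if (task == "active") tAfter else NA_real_,
    t_end = tAfter + if (task == "active") 0.3 else 0,
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Spiking
## ---------------------------------------------------------------------------

## Direction tuning over the 8 peripheral locations: von Mises kernel on the
## angle between location and the unit's preferred direction, normalized to
## peak 1. The centre location is untuned and receives the circular mean of
## the kernel over the 8 peripheral angles.
tuningWeight <- function(loc, prefLoc, kappa) {
  if (kappa == 0) return(rep(1, length(loc)))
  prefAngle <- locationAngle(prefLoc)
  periph <- peripheralLocations()
  kmean <- mean(exp(kappa * (cos(locationAngle(periph) - prefAngle) - 1)))
  w <- ifelse(loc == 4L, kmean,
              exp(kappa * (cos(locationAngle(loc) - prefAngle) - 1)))
  w
}

#' Simulate one unit's spikes on one trial
#'
#' Inhomogeneous Poisson process with intensity
#' \deqn{\lambda(t) = g \, [\,b\,(1 + (c-1) w \mathbf{1}_{cue}(t)
#'   + (d-1) w \mathbf{1}_{delay1}(t))\, m(t) + s\,(t - t_{cueoff})^+\,]}
#' where \eqn{g} is the trial's shared gain, \eqn{b} the baseline rate,
#' \eqn{c, d} the cue/delay gains, \eqn{w} the unit's tuning weight for the
#' trial's cue location, \eqn{m(t)} a match/nonmatch modulation of the
#' sample and second-delay epochs, and \eqn{s} the ramp slope toward the
#' choice targets. Sampling is by thinning, hence exact.
#'
#' @param unit list with fields \code{prefLoc}, \code{baseline},
#'   \code{responsive}, \code{matchPref} (+1/-1).
#' @param trial single-row trial data.frame (see
#'   \linkS4class{SessionRecording}).
#' @param gain shared multiplicative gain draw for this unit and trial.
#' @param sched effect-schedule row (a list).
#' @return numeric vector of spike times (s, trial-relative), sorted.
#' @export
synthesizeUnitSpikes <- function(unit, trial, gain, sched) {
  b <- unit$baseline
  resp <- isTRUE(unit$responsive)
  w <- if (resp) tuningWeight(trial$cue_location, unit$prefLoc,
                              sched$tuning_kappa) else 0
  cg <- if (resp) sched$cue_gain else 1
  dg <- if (resp) sched$delay_gain else 1
  ramp <- if (resp && trial$task == "active") sched$ramp_slope else 0
  m <- if (trial$task == "active" && resp) sched$match_info_strength else 0
  mSign <- if (isTRUE(trial$is_match)) 1 else -1
  mFac <- 1 + 0.5 * m * unit$matchPref * mSign
  tEnd <- trial$t_end
  rampEnd <- if (!is.na(trial$t_targets_on)) trial$t_targets_on else tEnd
  lambdaAt <- function(t) {
    inCue <- t >= trial$t_cue_on & t < trial$t_cue_off
    inD1 <- t >= trial$t_cue_off & t < trial$t_sample_on
    inSmp <- t >= trial$t_sample_on & t < rampEnd
    lam <- b * (1 + (cg - 1) * w * inCue + (dg - 1) * w * inD1) *
      ifelse(inSmp, mFac, 1)
    lam <- lam + ramp * pmax(0, pmin(t, rampEnd) - trial$t_cue_off) *
      (t < rampEnd)
    gain * lam
  }
  lamMax <- gain * (b * (1 + max(cg - 1, dg - 1, 0) * max(w, 1e-12)) *
                      max(1, mFac) +
                      max(ramp, 0) * (rampEnd - trial$t_cue_off)) * 1.0001
  failIf(!is.finite(lamMax) || lamMax < 0,
         "negative or non-finite intensity bound after composition")
  if (lamMax == 0) return(numeric(0))
  n <- stats::rpois(1, lamMax * tEnd)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, 0, tEnd))
  keep <- stats::runif(n) < lambdaAt(cand) / lamMax
  cand[keep]
}

#' Correlated shared gains for one trial block
#'
#' Multivariate log-normal gains implementing distance-dependent shared
#' variability: \eqn{\log g \sim N(-\sigma^2/2, \Sigma)} with
#' \eqn{\Sigma_{ij} = \sigma^2 \exp(-d_{ij}/L)}, where \eqn{d_{ij}} is the
#' physical distance between the electrodes carrying units i and j. Gains
#' have mean 1; pairwise spike-count correlations decay with distance at
#' scale \eqn{L}.
#'
#' @param electrodes electrode index per unit (0-based).
#' @param nTrials number of trials.
#' @param sd standard deviation of the log gain (\eqn{\sigma}).
#' @param corrLengthMm spatial correlation length \eqn{L} in mm (> 0).
#' @param grid a \linkS4class{GridGeometry}.
#' @return matrix nTrials x nUnits of gains.
#' @export
drawSharedGains <- function(electrodes, nTrials, sd, corrLengthMm, grid) {
  failIf(corrLengthMm <= 0, "spatial correlation length must be > 0")
  nU <- length(electrodes)
  if (sd == 0) return(matrix(1, nTrials, nU))
  D <- electrodeDistanceMatrix(grid, electrodes)
  C <- sd^2 * exp(-D / corrLengthMm)
  L <- tryCatch(chol(C + diag(1e-10 * sd^2, nU)),
                error = function(e)
                  stop("shared-gain covariance not positive definite",
                       call. = FALSE))
  Z <- matrix(stats::rnorm(nTrials * nU), nTrials, nU) %*% L
  exp(Z - sd^2 / 2)
}

## ---------------------------------------------------------------------------
## LFP
## ---------------------------------------------------------------------------

## Band-limited Gaussian noise of unit variance via FFT masking.
bandNoise <- function(n, fs, lo, hi) {
  z <- stats::rnorm(n)
  X <- stats::fft(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  mask <- f >= lo & f <= hi
  X[!mask] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate one LFP trial trace
#'
#' 1/f-shaped background noise plus band-limited alpha (8--14 Hz), beta
#' (20--45 Hz) and gamma (46--70 Hz) oscillations whose amplitudes are
#' multiplied by the schedule's per-band cue-epoch factors during the cue
#' presentation, plus an optional fixed-frequency line component for
#' exercising line removal.
#'
#' @param trial single-row trial data.frame.
#' @param sched effect-schedule row (list) supplying \code{alpha_amp},
#'   \code{beta_amp}, \code{gamma_amp}.
#' @param fs sampling rate, Hz (must be at least twice the top band edge).
#' @param lineHz line frequency to inject (0 = none), amplitude 1.
#' @return numeric vector of \code{floor(t_end * fs)} samples.
#' @export
synthesizeLfp <- function(trial, sched, fs, lineHz = 0) {
  failIf(fs < 2 * 70, "sampling rate below twice the top band edge")
  n <- floor(trial$t_end * fs)
  t <- (seq_len(n) - 1) / fs
  ## 1/f background: shape white noise by 1/sqrt(f)
  z <- stats::rnorm(n)
  X <- stats::fft(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 0.5, 0, 1 / sqrt(pmax(f, 0.5)))
  bg <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  sbg <- stats::sd(bg)
  if (sbg > 0) bg <- bg / sbg
  inCue <- t >= trial$t_cue_on & t < trial$t_cue_off
  bands <- list(alpha = c(8, 14), beta = c(20, 45), gamma = c(46, 70))
  baseAmp <- c(alpha = 0.8, beta = 1.0, gamma = 0.5)
  cueFac <- c(alpha = sched$alpha_amp, beta = sched$beta_amp,
              gamma = sched$gamma_amp)
  x <- bg
  for (bn in names(bands)) {
    osc <- bandNoise(n, fs, bands[[bn]][1], bands[[bn]][2])
    env <- baseAmp[[bn]] * ifelse(inCue, cueFac[[bn]], 1)
    x <- x + env * osc
  }
  if (lineHz > 0) x <- x + sin(2 * pi * lineHz * t)
  x
}

## ---------------------------------------------------------------------------
## Experiment assembly
## ---------------------------------------------------------------------------

#' Generate a synthetic multi-phase experiment
#'
#' Builds an \linkS4class{ExperimentDataset} emulating the staged training
#' design: sessions grouped into phases (pre-training, I--IV), each session
#' holding a passive block (all phases) followed by an active block (phases
#' I--IV); active phases I/II restrict the cue to the left/right pair of
#' locations, phase III on uses all nine. All randomness derives
#' hierarchically from the master seed, so identical configurations produce
#' byte-identical datasets and subsets regenerate identically.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return an \linkS4class{ExperimentDataset}.
#' @export
generateExperiment <- function(cfg) {
  failIf(!inherits(cfg, "SynthConfig"), "cfg must come from synthConfig()")
  grid <- cfg$grid
  nEl <- grid@nRows * grid@nCols
  sessions <- list()
  sid <- 0L
  hashCfg <- configHashOf(list(
    nUnits = cfg$nUnits, nTrialsPerCondition = cfg$nTrialsPerCondition,
    sessionsPerPhase = cfg$sessionsPerPhase, lfpRateHz = cfg$lfpRateHz,
    nLfpElectrodes = cfg$nLfpElectrodes, seed = cfg$seed,
    suaFraction = cfg$suaFraction, lineHz = cfg$lineHz,
    activeAccuracy = cfg$activeAccuracy,
    schedule = unclass(cfg$schedule)))
  for (pi in seq_along(phaseLevels())) {
    phase <- phaseLevels()[pi]
    for (si in seq_len(cfg$sessionsPerPhase)) {
      sid <- sid + 1L
      sSeed <- childSeed(cfg$seed, pi, si)
      sessions[[sid]] <- withSeed(sSeed, {
        generateSession(sid, phase, cfg, grid, nEl, sSeed)
      })
    }
  }
  ds <- ExperimentDataset(sessions, grid, cfg$timing, seed = cfg$seed,
                          configHash = hashCfg)
  validObject(ds)
  ds
}

generateSession <- function(sid, phase, cfg, grid, nEl, sSeed) {
  timing <- cfg$timing
  ## units: electrodes sampled uniformly; stable unit identities per session
  electrodes <- sample.int(nEl, cfg$nUnits, replace = TRUE) - 1L
  kinds <- ifelse(stats::runif(cfg$nUnits) < cfg$suaFraction, "SUA", "MUA")
  prefLocs <- sample(peripheralLocations(), cfg$nUnits, replace = TRUE)
  baselines <- NULL  # set per task below (baseline_rate may differ)
  matchPrefs <- sample(c(-1, 1), cfg$nUnits, replace = TRUE)
  tasks <- if (phase == "pre") "passive" else c("passive", "active")
  blocks <- list()
  startId <- 1L
  for (task in tasks) {
    blk <- withSeed(childSeed(sSeed, match(task, c("passive", "active"))), {
      buildTrialBlock(task, phase, timing, cfg$nTrialsPerCondition,
                      cfg$activeAccuracy, startId)
    })
    startId <- startId + nrow(blk)
    blocks[[task]] <- blk
  }
  tr <- do.call(rbind, unname(blocks))
  rownames(tr) <- NULL
  ## per-task responsiveness and gains
  unitSpikes <- replicate(cfg$nUnits, vector("list", nrow(tr)),
                          simplify = FALSE)
  for (task in tasks) {
    sched <- scheduleRow(cfg$schedule, phase, task)
    rows <- which(tr$task == task)
    respFlags <- withSeed(childSeed(sSeed, 11, match(task, tasks)), {
      stats::runif(cfg$nUnits) < sched$responsive_fraction
    })
    unitBase <- withSeed(childSeed(sSeed, 12, match(task, tasks)), {
      sched$baseline_rate * exp(stats::rnorm(cfg$nUnits, 0, 0.2) - 0.02)
    })
    gains <- withSeed(childSeed(sSeed, 13, match(task, tasks)), {
      drawSharedGains(electrodes, length(rows), sched$shared_noise_sd,
                      sched$spatial_corr_length_mm, grid)
    })
    for (u in seq_len(cfg$nUnits)) {
      unit <- list(prefLoc = prefLocs[u], baseline = unitBase[u],
                   responsive = respFlags[u], matchPref = matchPrefs[u])
      uSeed <- childSeed(sSeed, 20, match(task, tasks), u)
      unitSpikes[[u]][rows] <- withSeed(uSeed, {
        lapply(seq_along(rows), function(k)
          synthesizeUnitSpikes(unit, tr[rows[k], , drop = FALSE],
                               gains[k, u], sched))
      })
    }
  }
  units <- lapply(seq_len(cfg$nUnits), function(u) list(
    unit_id = sprintf("s%03d_u%03d", sid, u), kind = kinds[u],
    electrode = electrodes[u], spikes = unitSpikes[[u]]))
  ## LFP on a fixed subset of electrodes
  lfp <- list()
  if (cfg$nLfpElectrodes > 0) {
    lfpEls <- withSeed(childSeed(sSeed, 30), {
      sort(sample.int(nEl, min(cfg$nLfpElectrodes, nEl)) - 1L)
    })
    for (ei in seq_along(lfpEls)) {
      el <- lfpEls[ei]
      traces <- vector("list", nrow(tr))
      for (task in tasks) {
        sched <- scheduleRow(cfg$schedule, phase, task)
        rows <- which(tr$task == task)
        traces[rows] <- withSeed(childSeed(sSeed, 31, ei,
                                           match(task, tasks)), {
          lapply(rows, function(k)
            synthesizeLfp(tr[k, , drop = FALSE], sched, cfg$lfpRateHz,
                          cfg$lineHz))
        })
      }
      lfp[[as.character(el)]] <- traces
    }
  }
  SessionRecording(sid, phase, tr, units, lfp, cfg$lfpRateHz)
}
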