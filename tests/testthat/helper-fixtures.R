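# Shared fixtures built in code. The medium dataset is generated once per
# test run and reused by the decoding / correlation tests.

.fixtures <- new.env(parent = emptyenv())

smallExperiment <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- synthConfig(nUnits = 6, nTrialsPerCondition = 2,
                       sessionsPerPhase = 1, nLfpElectrodes = 1, seed = seed)
    .fixtures[[key]] <- generateExperiment(cfg)
  }
  .fixtures[[key]]
}

# 200 units across phases, trial counts adequate for decoding and pair
# correlations; no LFP (LFP paths are tested on purpose-built traces).
mediumExperiment <- function() {
  if (is.null(.fixtures$medium)) {
    cfg <- synthConfig(nUnits = 40, nTrialsPerCondition = 6,
                       sessionsPerPhase = 1, nLfpElectrodes = 0, seed = 101)
    .fixtures$medium <- generateExperiment(cfg)
  }
  .fixtures$medium
}

# A single canonical passive trial row (fixation 1 s, cue 0.5 s, 1.5 s
# delays).
passiveTrial <- function() {
  data.frame(trial_id = 1L, task = "passive", phase = "pre",
             cue_location = 0L, sample_location = 0L, is_match = TRUE,
             correct = TRUE, t_fixation_on = 0, t_cue_on = 1, t_cue_off = 1.5,
             t_sample_on = 3, t_sample_off = 3.5, t_targets_on = NA_real_,
             t_end = 5)
}

# Trial table with n trials per location, passive timing, all matches.
locationTrials <- function(nPerLoc, locs = 0:8) {
  cue <- rep(locs, each = nPerLoc)
  k <- length(cue)
  data.frame(trial_id = seq_len(k), task = "passive", phase = "pre",
             cue_location = as.integer(cue),
             sample_location = as.integer(cue), is_match = TRUE,
             correct = TRUE, t_fixation_on = 0, t_cue_on = 1, t_cue_off = 1.5,
             t_sample_on = 3, t_sample_off = 3.5, t_targets_on = NA_real_,
             t_end = 5)
}

# Homogeneous-Poisson unit over the full trial span (null unit).
poissonUnit <- function(trialTable, rate, id = "u1", kind = "MUA",
                        electrode = 0L) {
  spikes <- lapply(seq_len(nrow(trialTable)), function(i) {
    tEnd <- trialTable$t_end[i]
    sort(stats::runif(stats::rpois(1, rate * tEnd), 0, tEnd))
  })
  list(unit_id = id, kind = kind, electrode = as.integer(electrode),
       spikes = spikes)
}

# Decoding pool built directly from per-condition Poisson rate matrices;
# `sep` adds a planted rate offset at one preferred condition per unit.
syntheticPool <- function(nUnits, k, nBins, conditions, base = 5, sep = 0,
                          noiseSd = NULL) {
  units <- lapply(seq_len(nUnits), function(u) {
    pref <- sample(conditions, 1)
    byCond <- lapply(conditions, function(cc) {
      mu <- base + sep * (cc == pref)
      if (is.null(noiseSd)) {
        matrix(stats::rpois(k * nBins, mu), k, nBins)
      } else {
        matrix(stats::rnorm(k * nBins, mu, noiseSd), k, nBins)
      }
    })
    names(byCond) <- as.character(conditions)
    byCond
  })
  list(units = units, binCenters = seq_len(nBins), conditions = conditions)
}
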