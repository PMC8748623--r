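#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core S4 containers for chronic-array experiments
## ---------------------------------------------------------------------------

#' Electrode grid geometry
#'
#' Physical layout of the chronic microelectrode array: a regular grid of
#' electrodes at fixed pitch. Electrodes are indexed 0-based, row-major.
#'
#' @slot nRows,nCols integer grid dimensions (default 8 x 8).
#' @slot pitchMm centre-to-centre spacing of adjacent electrodes in mm
#'   (default 0.75, covering 5.25 mm x 5.25 mm for the 8 x 8 array).
#' @export
setClass("GridGeometry",
  representation(nRows = "integer", nCols = "integer", pitchMm = "numeric"),
  prototype(nRows = 8L, nCols = 8L, pitchMm = 0.75))

setValidity("GridGeometry", function(object) {
  msgs <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L)
    msgs <- c(msgs, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || object@nCols < 1L)
    msgs <- c(msgs, "nCols must be a single positive integer")
  if (length(object@pitchMm) != 1L || !is.finite(object@pitchMm) ||
      object@pitchMm <= 0)
    msgs <- c(msgs, "pitchMm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' @param nRows,nCols grid dimensions.
#' @param pitchMm electrode pitch in mm.
#' @rdname GridGeometry-class
#' @export
GridGeometry <- function(nRows = 8L, nCols = 8L, pitchMm = 0.75) {
  new("GridGeometry", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitchMm = as.numeric(pitchMm))
}

#' Trial timing template
#'
#' Durations of the task epochs. Every trial starts with a fixation period,
#' followed by cue, first delay, sample (second stimulus) and second delay;
#' active trials end with the onset of the choice targets. Delay durations
#' depend on training phase: fixed short delays in phases I--III, variable
#' delays in phase IV, and 1.5 s delays in the passive task (which mirrors
#' the final configuration of the active task).
#'
#' @slot fixationS fixation duration, s (default 1).
#' @slot cueS cue (first stimulus) duration, s (default 0.5; the source
#'   protocol leaves this unstated, so it is configurable).
#' @slot sampleS second-stimulus duration, s (default 0.5).
#' @slot passiveDelayS delay duration in the passive task, s (1.5).
#' @slot activeDelayS named vector of fixed delays for active phases
#'   I, II, III, s.
#' @slot phase4DelayRangeS length-2 range of the variable phase-IV delays, s;
#'   must lie within [0.25, 1.5].
#' @export
setClass("TaskTiming",
  representation(fixationS = "numeric", cueS = "numeric", sampleS = "numeric",
                 passiveDelayS = "numeric", activeDelayS = "numeric",
                 phase4DelayRangeS = "numeric"),
  prototype(fixationS = 1, cueS = 0.5, sampleS = 0.5, passiveDelayS = 1.5,
            activeDelayS = c(I = 0.25, II = 0.25, III = 0.25),
            phase4DelayRangeS = c(0.25, 1.5)))

setValidity("TaskTiming", function(object) {
  msgs <- character()
  durs <- c(object@fixationS, object@cueS, object@sampleS,
            object@passiveDelayS, object@activeDelayS)
  if (any(!is.finite(durs)) || any(durs <= 0))
    msgs <- c(msgs, "all durations must be positive and finite")
  r <- object@phase4DelayRangeS
  if (length(r) != 2L || r[1] > r[2])
    msgs <- c(msgs, "phase4DelayRangeS must be an increasing length-2 range")
  else if (r[1] < 0.25 - 1e-12 || r[2] > 1.5 + 1e-12)
    msgs <- c(msgs, "phase-IV delays must lie within [0.25, 1.5] s")
  if (!identical(sort(names(object@activeDelayS)), sort(c("I", "II", "III"))))
    msgs <- c(msgs, "activeDelayS must be named I, II, III")
  if (length(msgs)) msgs else TRUE
})

#' @param fixationS,cueS,sampleS,passiveDelayS,activeDelayS,phase4DelayRangeS
#'   see slots.
#' @rdname TaskTiming-class
#' @export
TaskTiming <- function(fixationS = 1, cueS = 0.5, sampleS = 0.5,
                       passiveDelayS = 1.5,
                       activeDelayS = c(I = 0.25, II = 0.25, III = 0.25),
                       phase4DelayRangeS = c(0.25, 1.5)) {
  new("TaskTiming", fixationS = fixationS, cueS = cueS, sampleS = sampleS,
      passiveDelayS = passiveDelayS, activeDelayS = activeDelayS,
      phase4DelayRangeS = phase4DelayRangeS)
}

#' One recording session (day)
#'
#' A day's recordings: the trial table (passive block followed, from phase I
#' on, by the active block), spike trains of all units, and LFP traces.
#'
#' The trial table has one row per trial with columns \code{trial_id},
#' \code{task} ("passive"/"active"), \code{phase}, \code{cue_location},
#' \code{sample_location} (0--8, row-major on the 3 x 3 stimulus grid,
#' 4 = centre), \code{is_match}, \code{correct}, and event times in seconds
#' from trial start: \code{t_fixation_on}, \code{t_cue_on}, \code{t_cue_off},
#' \code{t_sample_on}, \code{t_sample_off}, \code{t_targets_on} (NA on
#' passive trials) and \code{t_end}.
#'
#' Each element of \code{units} is a list with fields \code{unit_id},
#' \code{kind} ("MUA"/"SUA"), \code{electrode} (0-based index into the grid)
#' and \code{spikes}, a list of per-trial spike-time vectors (seconds,
#' trial-relative) parallel to the trial table.
#'
#' \code{lfp} is a list named by electrode index, each element a list of
#' per-trial sample vectors at \code{lfpRateHz}.
#'
#' @export
setClass("SessionRecording",
  representation(sessionId = "integer", phase = "character",
                 trials = "data.frame", units = "list", lfp = "list",
                 lfpRateHz = "numeric"))

trialColumns <- function() {
  c("trial_id", "task", "phase", "cue_location", "sample_location",
    "is_match", "correct", "t_fixation_on", "t_cue_on", "t_cue_off",
    "t_sample_on", "t_sample_off", "t_targets_on", "t_end")
}

validateTrials <- function(tr) {
  msgs <- character()
  missing <- setdiff(trialColumns(), names(tr))
  if (length(missing))
    return(sprintf("trial table missing column(s): %s",
                   paste(missing, collapse = ", ")))
  bad <- which(tr$is_match != (tr$cue_location == tr$sample_location))
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "is_match inconsistent with cue/sample locations on trial(s) %s",
      paste(utils::head(tr$trial_id[bad], 5), collapse = ", ")))
  if (!all(tr$cue_location %in% 0:8) || !all(tr$sample_location %in% 0:8))
    msgs <- c(msgs, "stimulus locations must be in 0..8")
  for (i in seq_len(nrow(tr))) {
    ev <- c(tr$t_fixation_on[i], tr$t_cue_on[i], tr$t_cue_off[i],
            tr$t_sample_on[i], tr$t_sample_off[i])
    if (tr$task[i] == "active") {
      if (is.na(tr$t_targets_on[i])) {
        msgs <- c(msgs, sprintf("active trial %d lacks targets-on time",
                                tr$trial_id[i]))
        next
      }
      ev <- c(ev, tr$t_targets_on[i])
    } else if (!is.na(tr$t_targets_on[i])) {
      msgs <- c(msgs, sprintf("passive trial %d has a targets-on event",
                              tr$trial_id[i]))
    }
    if (any(diff(ev) <= 0) || tr$t_end[i] < ev[length(ev)])
      msgs <- c(msgs, sprintf("event times not strictly increasing on trial %d",
                              tr$trial_id[i]))
    if (length(msgs) >= 5) break  # cap the report
  }
  msgs
}

setValidity("SessionRecording", function(object) {
  msgs <- character()
  if (!object@phase %in% phaseLevels())
    msgs <- c(msgs, "phase must be one of pre, I, II, III, IV")
  msgs <- c(msgs, validateTrials(object@trials))
  n <- nrow(object@trials)
  for (u in object@units) {
    if (!all(c("unit_id", "kind", "electrode", "spikes") %in% names(u))) {
      msgs <- c(msgs, "unit entries need unit_id, kind, electrode, spikes")
      break
    }
    if (length(u$spikes) != n) {
      msgs <- c(msgs, sprintf("unit %s: %d spike lists for %d trials",
                              u$unit_id, length(u$spikes), n))
      next
    }
    for (i in seq_len(n)) {
      s <- u$spikes[[i]]
      if (length(s) && (min(s) < 0 || max(s) > object@trials$t_end[i] + 1e-9)) {
        msgs <- c(msgs, sprintf("unit %s trial %d: spike times outside trial",
                                u$unit_id, object@trials$trial_id[i]))
        break
      }
    }
  }
  if (length(object@lfp)) {
    if (length(object@lfpRateHz) != 1L || object@lfpRateHz < 500)
      msgs <- c(msgs, "lfpRateHz must be a single value >= 500")
    for (el in names(object@lfp)) {
      tracks <- object@lfp[[el]]
      if (length(tracks) != n) {
        msgs <- c(msgs, sprintf("electrode %s: %d LFP traces for %d trials",
                                el, length(tracks), n))
        next
      }
      expected <- floor(object@trials$t_end * object@lfpRateHz)
      lens <- lengths(tracks)
      bad <- which(abs(lens - expected) > 1)
      if (length(bad))
        msgs <- c(msgs, sprintf(
          "electrode %s trial %d: LFP length %d != expected %d",
          el, object@trials$trial_id[bad[1]], lens[bad[1]], expected[bad[1]]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @param sessionId integer date-index of the session.
#' @param phase training phase label.
#' @param trials trial table (see class description).
#' @param units list of unit entries.
#' @param lfp list of per-electrode LFP trial traces.
#' @param lfpRateHz LFP sampling rate in Hz.
#' @rdname SessionRecording-class
#' @export
SessionRecording <- function(sessionId, phase, trials, units = list(),
                             lfp = list(), lfpRateHz = 500) {
  new("SessionRecording", sessionId = as.integer(sessionId), phase = phase,
      trials = trials, units = units, lfp = lfp,
      lfpRateHz = as.numeric(lfpRateHz))
}

#' A longitudinal experiment: ordered sessions plus provenance
#'
#' Sessions are ordered by date-index and phase labels are non-decreasing
#' over the training order pre <= I <= II <= III <= IV.
#'
#' @slot sessions list of \linkS4class{SessionRecording}.
#' @slot grid the \linkS4class{GridGeometry} shared by all sessions.
#' @slot timing the \linkS4class{TaskTiming} template.
#' @slot seed master generator seed (NA for real data).
#' @slot configHash hash of the generating configuration.
#' @export
setClass("ExperimentDataset",
  representation(sessions = "list", grid = "GridGeometry",
                 timing = "TaskTiming", seed = "integer",
                 configHash = "character"))

setValidity("ExperimentDataset", function(object) {
  msgs <- character()
  ids <- vapply(object@sessions, function(s) s@sessionId, integer(1))
  if (length(ids) > 1 && any(diff(ids) <= 0))
    msgs <- c(msgs, "sessions must be strictly ordered by date-index")
  ph <- match(vapply(object@sessions, function(s) s@phase, character(1)),
              phaseLevels())
  if (length(ph) > 1 && any(diff(ph) < 0))
    msgs <- c(msgs, "phase labels must be non-decreasing across sessions")
  nEl <- object@grid@nRows * object@grid@nCols
  for (s in object@sessions) {
    el <- vapply(s@units, function(u) as.integer(u$electrode), integer(1))
    if (length(el) && (any(el < 0) || any(el >= nEl))) {
      msgs <- c(msgs, sprintf("session %d: electrode index outside grid",
                              s@sessionId))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @param sessions,grid,timing,seed,configHash see slots.
#' @rdname ExperimentDataset-class
#' @export
ExperimentDataset <- function(sessions, grid = GridGeometry(),
                              timing = TaskTiming(), seed = NA_integer_,
                              configHash = "") {
  new("ExperimentDataset", sessions = sessions, grid = grid, timing = timing,
      seed = as.integer(seed), configHash = configHash)
}

#' Pseudo-population decoding result
#'
#' Per-time-bin classification accuracies over repeated cross-validated runs
#' on freshly resampled pseudo-populations, the matching shuffled-label null
#' samples, and per-bin significance relative to the null 95% interval.
#'
#' @slot label decoded variable: "location8" (8 peripheral cue locations) or
#'   "match2" (match/nonmatch).
#' @slot binCenters bin centres in seconds from cue onset.
#' @slot accuracy matrix bins x samples (samples = repeats x resamples).
#' @slot nullAccuracy matrix bins x null samples (shuffled labels).
#' @slot chance chance level (1/8 or 1/2).
#' @slot flags per-bin logical: mean accuracy outside the null 95% interval.
#' @slot nullInterval 2 x bins matrix of the null 2.5/97.5 percentiles.
#' @slot zP per-bin two-sided z-test p-value actual vs null.
#' @export
setClass("DecodingResult",
  representation(label = "character", binCenters = "numeric",
                 accuracy = "matrix", nullAccuracy = "matrix",
                 chance = "numeric", flags = "logical",
                 nullInterval = "matrix", zP = "numeric"))

setValidity("DecodingResult", function(object) {
  msgs <- character()
  if (any(object@accuracy < -1e-12) || any(object@accuracy > 1 + 1e-12))
    msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (nrow(object@accuracy) != length(object@binCenters))
    msgs <- c(msgs, "accuracy rows must match binCenters")
  if (length(msgs)) msgs else TRUE
})

#' Demixed PCA fit
#'
#' Per-marginalization encoder/decoder pairs from regularized reduced-rank
#' regression of each marginalized average onto the full centred data, with
#' an explained-variance table.
#'
#' @slot encoders,decoders named lists (one per marginalization) of weight
#'   matrices: encoder units x components, decoder components x units.
#' @slot varianceTable data.frame (marginalization, component, evar_share,
#'   cum_evar_share) with shares of total centred variance.
#' @slot lambda ridge penalty used.
#' @slot unitMeans per-unit means removed before fitting.
#' @slot dims dimensions (units, stimuli, decisions, time bins).
#' @export
setClass("DpcaFit",
  representation(encoders = "list", decoders = "list",
                 varianceTable = "data.frame", lambda = "numeric",
                 unitMeans = "numeric", dims = "integer"))

setValidity("DpcaFit", function(object) {
  vt <- object@varianceTable
  if (nrow(vt) && (any(vt$evar_share < -1e-8) || sum(vt$evar_share) > 1 + 1e-6))
    return("explained-variance shares must be in [0, 1] and total <= 1")
  TRUE
})
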