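## Responsiveness screening, epoch rates, best location, population PSTH.

epochNames <- function() c("fixation", "cue", "delay1", "sample", "delay2")

## Start/end of a named epoch on one trial row, from its event times.
## All windows are half-open [start, end).
epochWindow <- function(trial, epoch) {
  end2 <- if (!is.na(trial$t_targets_on)) trial$t_targets_on else trial$t_end
  switch(epoch,
    fixation = c(trial$t_fixation_on, trial$t_cue_on),
    cue      = c(trial$t_cue_on, trial$t_cue_off),
    delay1   = c(trial$t_cue_off, trial$t_sample_on),
    sample   = c(trial$t_sample_on, trial$t_sample_off),
    delay2   = c(trial$t_sample_off, end2),
    stop(sprintf("unknown epoch '%s'", epoch), call. = FALSE))
}

#' Firing rate of a unit in a trial epoch
#'
#' Spike count in the half-open epoch window [start, end) divided by its
#' duration. Spikes exactly at the epoch end are excluded.
#'
#' @param spikes numeric vector of trial-relative spike times (s).
#' @param trial single-row trial data.frame.
#' @param epoch one of "fixation", "cue", "delay1", "sample", "delay2".
#' @return rate in spikes/s.
#' @export
epochRate <- function(spikes, trial, epoch) {
  w <- epochWindow(trial, epoch)
  dur <- w[2] - w[1]
  failIf(!is.finite(dur) || dur <= 0, "epoch '%s' has non-positive duration",
         epoch)
  countInWindow(spikes, w[1], w[2]) / dur
}

#' Per-trial epoch rates for one unit
#'
#' @param unit a unit entry (list with \code{spikes} parallel to
#'   \code{trials}).
#' @param trials trial table (subset rows must match the spike list indices
#'   given in \code{rows}).
#' @param epoch epoch name.
#' @param rows integer row indices into \code{trials} / the spike list
#'   (default: all).
#' @return numeric vector of rates, one per requested trial.
#' @export
epochRates <- function(unit, trials, epoch, rows = seq_len(nrow(trials))) {
  vapply(rows, function(i)
    epochRate(unit$spikes[[i]], trials[i, , drop = FALSE], epoch), numeric(1))
}

#' Multi-location responsiveness screen (one-way ANOVA)
#'
#' A unit recorded under several cue locations is responsive when its mean
#' firing rate differs across locations in either the cue epoch or the first
#' delay epoch, by one-way ANOVA at level \code{alpha} on correct trials.
#'
#' @param unit unit entry.
#' @param trials trial table for one task block.
#' @param alpha significance level (default 0.05).
#' @param correctOnly restrict to correct trials (default TRUE).
#' @return list with \code{unit_id}, \code{evaluable}, \code{is_responsive},
#'   \code{test} = "anova_locations", \code{p_cue}, \code{p_delay1},
#'   \code{best_cue_location}, \code{best_delay1_location}.
#' @export
screenResponsiveMultiLocation <- function(unit, trials, alpha = 0.05,
                                          correctOnly = TRUE) {
  rows <- which(if (correctOnly) trials$correct else rep(TRUE, nrow(trials)))
  locs <- trials$cue_location[rows]
  tab <- table(locs)
  if (sum(tab >= 2) < 2) {
    return(list(unit_id = unit$unit_id, evaluable = FALSE,
                is_responsive = NA, test = "anova_locations",
                p_cue = NA_real_, p_delay1 = NA_real_,
                best_cue_location = NA_integer_,
                best_delay1_location = NA_integer_))
  }
  keep <- rows[locs %in% as.integer(names(tab)[tab >= 2])]
  loc <- factor(trials$cue_location[keep])
  pOf <- function(epoch) {
    r <- epochRates(unit, trials, epoch, keep)
    if (stats::sd(r) == 0) return(1)  # degenerate: no variance anywhere
    fit <- stats::aov(r ~ loc)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }
  pCue <- pOf("cue")
  pD1 <- pOf("delay1")
  list(unit_id = unit$unit_id, evaluable = TRUE,
       is_responsive = (pCue < alpha) || (pD1 < alpha),
       test = "anova_locations", p_cue = pCue, p_delay1 = pD1,
       best_cue_location = bestLocation(unit, trials, "cue", keep),
       best_delay1_location = bestLocation(unit, trials, "delay1", keep))
}

#' Single-location responsiveness screen (paired elevation test)
#'
#' For blocks with a single cue location, a unit is responsive when its cue-
#' or first-delay-epoch rate significantly exceeds the fixation rate (paired
#' t-test at level \code{alpha}, with the stimulus mean above the fixation
#' mean). Multi-unit records additionally require a minimum 10% rate
#' increase during the stimulus presentation over the fixation interval, a
#' guard against threshold-crossing false positives; sorted single units
#' omit that proportional criterion.
#'
#' @param unit unit entry (its \code{kind} field selects the MUA gate).
#' @param trials trial table for one task block.
#' @param alpha significance level.
#' @param minIncrease proportional cue-rate increase required for MUA
#'   (default 0.10).
#' @param correctOnly restrict to correct trials.
#' @return list as in \code{\link{screenResponsiveMultiLocation}} with
#'   \code{test} = "paired_vs_fixation" and \code{percent_increase}.
#' @export
screenResponsiveSingleLocation <- function(unit, trials, alpha = 0.05,
                                           minIncrease = 0.10,
                                           correctOnly = TRUE) {
  rows <- which(if (correctOnly) trials$correct else rep(TRUE, nrow(trials)))
  if (length(rows) < 5) {
    return(list(unit_id = unit$unit_id, evaluable = FALSE,
                is_responsive = NA, test = "paired_vs_fixation",
                p_cue = NA_real_, p_delay1 = NA_real_,
                percent_increase = NA_real_,
                best_cue_location = NA_integer_,
                best_delay1_location = NA_integer_))
  }
  fix <- epochRates(unit, trials, "fixation", rows)
  cue <- epochRates(unit, trials, "cue", rows)
  d1 <- epochRates(unit, trials, "delay1", rows)
  pairedP <- function(x) {
    d <- x - fix
    if (stats::sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
    stats::t.test(x, fix, paired = TRUE)$p.value
  }
  pCue <- pairedP(cue)
  pD1 <- pairedP(d1)
  elevCue <- mean(cue) > mean(fix)
  elevD1 <- mean(d1) > mean(fix)
  pctInc <- if (mean(fix) > 0) mean(cue) / mean(fix) - 1 else Inf
  cueOk <- (pCue < alpha) && elevCue &&
    (unit$kind != "MUA" || pctInc >= minIncrease)
  d1Ok <- (pD1 < alpha) && elevD1
  list(unit_id = unit$unit_id, evaluable = TRUE,
       is_responsive = cueOk || d1Ok, test = "paired_vs_fixation",
       p_cue = pCue, p_delay1 = pD1, percent_increase = pctInc,
       best_cue_location = bestLocation(unit, trials, "cue", rows),
       best_delay1_location = bestLocation(unit, trials, "delay1", rows))
}

#' Cue location eliciting the strongest epoch response
#'
#' Location with the maximal mean epoch rate; exact ties break to the lowest
#' location index.
#'
#' @param unit unit entry.
#' @param trials trial table.
#' @param epoch epoch name.
#' @param rows trial row indices to use (default: all).
#' @return location index (0--8).
#' @export
bestLocation <- function(unit, trials, epoch, rows = seq_len(nrow(trials))) {
  failIf(length(rows) < 1, "no trials available")
  r <- epochRates(unit, trials, epoch, rows)
  means <- tapply(r, trials$cue_location[rows], mean)
  locs <- as.integer(names(means))
  locs[order(-means, locs)][1]
}

#' Population PSTH at each unit's best location
#'
#' Trial-averaged firing rate per unit in half-open bins aligned to cue
#' onset, using each unit's best-location trials, with optional subtraction
#' of the unit's mean fixation rate. The window is clipped to the extent
#' shared by all selected trials; mixing trials of unequal post-cue duration
#' beyond that extent raises an error rather than silently truncating.
#'
#' @param units list of unit entries.
#' @param trials trial table shared by the units.
#' @param binS bin width, s (default 0.05).
#' @param window length-2 window in seconds relative to cue onset; default
#'   spans from the start of fixation to the common trial extent.
#' @param bestLocations optional integer vector of per-unit locations
#'   (default: computed from the cue epoch).
#' @param baselineSubtract subtract each unit's mean fixation-epoch rate.
#' @param correctOnly restrict to correct trials.
#' @return list with \code{binCenters}, \code{rateMatrix} (units x bins),
#'   \code{mean}, \code{sem}.
#' @export
populationPsth <- function(units, trials, binS = 0.05, window = NULL,
                           bestLocations = NULL, baselineSubtract = FALSE,
                           correctOnly = TRUE) {
  rows0 <- which(if (correctOnly) trials$correct else rep(TRUE, nrow(trials)))
  failIf(length(rows0) == 0, "no usable trials")
  relEnd <- trials$t_end[rows0] - trials$t_cue_on[rows0]
  relStart <- -(trials$t_cue_on[rows0] - trials$t_fixation_on[rows0])
  common <- c(max(relStart), min(relEnd))
  if (is.null(window)) {
    window <- common
  } else {
    failIf(window[1] < min(relStart) - 1e-9 || window[2] > max(relEnd) + 1e-9,
           "window exceeds trial bounds")
    failIf(window[2] > common[2] + 1e-9,
           "window exceeds the common trial extent; mixed post-cue durations need explicit segment alignment")
  }
  starts <- seq(window[1], window[2] - binS + 1e-12, by = binS)
  centers <- starts + binS / 2
  rateMatrix <- matrix(NA_real_, length(units), length(starts))
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    loc <- if (!is.null(bestLocations)) bestLocations[ui] else
      bestLocation(u, trials, "cue", rows0)
    rows <- rows0[trials$cue_location[rows0] == loc]
    if (!length(rows)) rows <- rows0
    counts <- matrix(0, length(rows), length(starts))
    for (k in seq_along(rows)) {
      s <- u$spikes[[rows[k]]] - trials$t_cue_on[rows[k]]
      counts[k, ] <- vapply(starts, function(st)
        countInWindow(s, st, st + binS), numeric(1))
    }
    rate <- colMeans(counts) / binS
    if (baselineSubtract) {
      rate <- rate - mean(epochRates(u, trials, "fixation", rows))
    }
    rateMatrix[ui, ] <- rate
  }
  list(binCenters = centers, rateMatrix = rateMatrix,
       mean = colMeans(rateMatrix),
       sem = apply(rateMatrix, 2, stats::sd) / sqrt(nrow(rateMatrix)))
}

#' Screen every unit of a session block
#'
#' Dispatches to the multi-location ANOVA screen when the block contains two
#' or more cue locations and to the paired single-location screen otherwise
#' (active phases I/II, where the cue is fixed).
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param task "passive" or "active".
#' @param alpha significance level.
#' @return data.frame, one row per unit.
#' @export
screenSession <- function(session, task, alpha = 0.05) {
  tr <- trials(session)
  blk <- tr[tr$task == task, , drop = FALSE]
  failIf(nrow(blk) == 0, "session %d has no %s trials", session@sessionId,
         task)
  rowIdx <- which(tr$task == task)
  multi <- length(unique(blk$cue_location)) > 1
  res <- lapply(spikeUnits(session), function(u) {
    uu <- u
    uu$spikes <- u$spikes[rowIdx]
    out <- if (multi) screenResponsiveMultiLocation(uu, blk, alpha)
      else screenResponsiveSingleLocation(uu, blk, alpha)
    out$kind <- u$kind
    out$electrode <- u$electrode
    out$percent_increase <- out$percent_increase %||% NA_real_
    out
  })
  do.call(rbind, lapply(res, function(x)
    data.frame(unit_id = x$unit_id, kind = x$kind, electrode = x$electrode,
               evaluable = x$evaluable, is_responsive = x$is_responsive,
               test = x$test, p_cue = x$p_cue, p_delay1 = x$p_delay1,
               percent_increase = x$percent_increase,
               best_cue_location = x$best_cue_location,
               best_delay1_location = x$best_delay1_location,
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
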