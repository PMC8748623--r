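## Fixation-period spike-count noise correlation, distance profiles, and
## phase/task comparisons.

#' Fixation-period spike counts
#'
#' Per-trial spike counts of one unit in the fixation window (the 1 s
#' pre-cue interval, identical across tasks and phases), trial order
#' preserved.
#'
#' @param unit unit entry.
#' @param trials trial table.
#' @param rows trial row indices (default: all).
#' @return integer-valued numeric vector, one count per trial.
#' @export
fixationCounts <- function(unit, trials, rows = seq_len(nrow(trials))) {
  vapply(rows, function(i) {
    w <- epochWindow(trials[i, , drop = FALSE], "fixation")
    failIf(!is.finite(w[1]) || !is.finite(w[2]) || w[2] <= w[1],
           "missing fixation epoch on trial %d", trials$trial_id[i])
    countInWindow(unit$spikes[[i]], w[1], w[2])
  }, numeric(1))
}

#' Pairwise spike-count (noise) correlation
#'
#' Pearson correlation between two units' per-trial fixation counts.
#' Constant count vectors leave the coefficient undefined; such pairs are
#' signalled (NA) so callers exclude them rather than treating them as zero.
#'
#' @param countsA,countsB equal-length per-trial count vectors.
#' @param minTrials minimum trials required (default 20).
#' @return Pearson r, or NA if either vector is constant.
#' @export
pairCorrelation <- function(countsA, countsB, minTrials = 20) {
  failIf(length(countsA) != length(countsB),
         "count vectors differ in length")
  failIf(length(countsA) < minTrials,
         "need at least %d trials, got %d", minTrials, length(countsA))
  if (stats::sd(countsA) == 0 || stats::sd(countsB) == 0) return(NA_real_)
  stats::cor(countsA, countsB)
}

#' Noise-correlation table for all simultaneous pairs of one session block
#'
#' One record per unordered pair of simultaneously recorded units, with the
#' fixation-count Pearson correlation and the physical distance between the
#' electrodes (0 for pairs on the same electrode). Pairs with undefined
#' correlation (a constant count vector) are dropped.
#'
#' @param session a \linkS4class{SessionRecording}.
#' @param task "passive" or "active".
#' @param grid the \linkS4class{GridGeometry} of the array.
#' @param minTrials minimum trials per pair (default 20).
#' @return data.frame with columns unit_a, unit_b, session, phase, task, r,
#'   n_trials, distance_mm.
#' @export
correlationTable <- function(session, task, grid, minTrials = 20) {
  tr <- trials(session)
  rows <- which(tr$task == task)
  units <- spikeUnits(session)
  failIf(length(units) < 2, "session needs at least 2 units")
  counts <- lapply(units, function(u) fixationCounts(u, tr, rows))
  out <- list()
  k <- 0L
  for (i in seq_len(length(units) - 1)) {
    for (j in seq(i + 1, length(units))) {
      r <- pairCorrelation(counts[[i]], counts[[j]], minTrials)
      if (is.na(r)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        unit_a = units[[i]]$unit_id, unit_b = units[[j]]$unit_id,
        session = session@sessionId, phase = session@phase, task = task,
        r = r, n_trials = length(rows),
        distance_mm = electrodeDistance(grid, units[[i]]$electrode,
                                        units[[j]]$electrode),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Noise-correlation pair table for a whole experiment
#'
#' @param ds an \linkS4class{ExperimentDataset}.
#' @param task task block to use.
#' @param minTrials minimum trials per pair.
#' @return row-bound \code{\link{correlationTable}} across sessions.
#' @export
experimentCorrelationTable <- function(ds, task, minTrials = 20) {
  tabs <- lapply(sessions(ds), function(s) {
    if (!task %in% trials(s)$task) return(data.frame())
    correlationTable(s, task, arrayGeometry(ds), minTrials)
  })
  do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
}

#' Phase comparison of noise correlation with distance as covariate
#'
#' Analysis of covariance: the linear model \code{r ~ phase + distance_mm}
#' with phase categorical and distance continuous; the phase effect is the
#' F-test on the phase factor after accounting for distance.
#'
#' @param records pair-correlation data.frame (columns \code{r},
#'   \code{phase}, \code{distance_mm}).
#' @return list with \code{F}, \code{df}, \code{p} for the phase factor,
#'   \code{distance_coef} (fitted slope on distance) and the full
#'   \code{anova} table.
#' @export
phaseComparisonAncova <- function(records) {
  failIf(length(unique(records$phase)) < 2,
         "need at least 2 phases for the phase comparison")
  byPhase <- tapply(records$distance_mm, records$phase,
                    function(d) length(unique(d)))
  failIf(any(byPhase < 2),
         "degenerate design: phase(s) %s carry fewer than 2 distinct distances",
         paste(names(byPhase)[byPhase < 2], collapse = ", "))
  records$phase <- factor(records$phase,
                          levels = intersect(phaseLevels(), records$phase))
  fit <- stats::lm(r ~ phase + distance_mm, data = records)
  ## phase F-test adjusted for distance: compare against distance-only model
  fit0 <- stats::lm(r ~ distance_mm, data = records)
  an <- stats::anova(fit0, fit)
  list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]), p = an$`Pr(>F)`[2],
       distance_coef = unname(stats::coef(fit)["distance_mm"]),
       anova = stats::anova(fit))
}

#' Two-way phase x task ANOVA on same-electrode pairs
#'
#' Factorial comparison of noise correlation for pairs recorded on the same
#' electrode (distance 0), with training phase and task as factors.
#'
#' @param records pair table containing passive and active records.
#' @return list with F, df and p for the phase and task main effects.
#' @export
sameElectrodePhaseTaskAnova <- function(records) {
  same <- records[records$distance_mm == 0, , drop = FALSE]
  failIf(nrow(same) < 4, "too few same-electrode pairs")
  failIf(length(unique(same$phase)) < 2 || length(unique(same$task)) < 2,
         "need >= 2 phases and both tasks among same-electrode pairs")
  same$phase <- factor(same$phase,
                       levels = intersect(phaseLevels(), same$phase))
  same$task <- factor(same$task)
  fit <- stats::aov(r ~ phase + task, data = same)
  tab <- summary(fit)[[1]]
  list(phase = list(F = tab["phase", "F value"],
                    df = c(tab["phase", "Df"], tab["Residuals", "Df"]),
                    p = tab["phase", "Pr(>F)"]),
       task = list(F = tab["task", "F value"],
                   df = c(tab["task", "Df"], tab["Residuals", "Df"]),
                   p = tab["task", "Pr(>F)"]))
}

#' Mean correlation by electrode-distance bin
#'
#' Display binning of pair correlations over inter-electrode distance; the
#' statistics in \code{\link{phaseComparisonAncova}} always use continuous
#' distance.
#'
#' @param records pair table.
#' @param breaks distance bin edges in mm (right-open; last bin catches the
#'   remainder).
#' @return data.frame (bin, n, mean_r, sem_r).
#' @export
correlationByDistance <- function(records,
                                  breaks = c(0, 0.374, 1.05, 1.51, Inf)) {
  bin <- cut(records$distance_mm, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  agg <- tapply(records$r, bin, function(x)
    c(n = length(x), mean_r = mean(x),
      sem_r = stats::sd(x) / sqrt(length(x))))
  keep <- !vapply(agg, is.null, logical(1))
  out <- do.call(rbind, agg[keep])
  data.frame(bin = names(agg)[keep], out, row.names = NULL,
             stringsAsFactors = FALSE)
}
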