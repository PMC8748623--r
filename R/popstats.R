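## Sliding-window three-way ANOVA of task-variable encoding and the
## binomial test on the fraction of selective units.

#' Sliding-window three-way ANOVA
#'
#' For every unit and sliding time bin (default 200 ms bins advanced by
#' 50 ms), fits a linear model of the binned firing rate on three factors:
#' first-stimulus (cue) location, second-stimulus (sample) location, and
#' decision type (match/nonmatch), and records the main-effect p-values.
#' Main effects only: because the match label is determined by the two
#' locations, the full-interaction model is aliased with the decision
#' factor; the decision effect is therefore estimated from the two-level
#' match label with the location factors as covariates.
#'
#' @param units list of unit entries (spike lists parallel to
#'   \code{trials}).
#' @param trialTable trial table carrying \code{cue_location},
#'   \code{sample_location} and \code{is_match}.
#' @param binS bin width, s (default 0.2).
#' @param stepS bin step, s (default 0.05).
#' @param window length-2 analysis window in seconds relative to cue onset;
#'   default from fixation start to the common trial extent.
#' @param alpha significance level for the per-bin selectivity flags.
#' @return list of class \code{SlidingAnovaResult}: \code{binCenters},
#'   \code{p} (array units x bins x 3 factors), \code{flagged} (logical,
#'   same shape), \code{fractions} (bins x factors), \code{binomP} (bins x
#'   factors, from \code{\link{selectiveFractionTest}}), \code{alpha},
#'   \code{nUnits}.
#' @export
slidingThreeWayAnova <- function(units, trialTable, binS = 0.2,
                                 stepS = 0.05, window = NULL, alpha = 0.05) {
  tr <- trialTable
  factors <- c("cue_location", "sample_location", "decision")
  fCue <- factor(tr$cue_location)
  fSmp <- factor(tr$sample_location)
  fDec <- factor(tr$is_match)
  failIf(nlevels(fCue) < 2 && nlevels(fSmp) < 2 && nlevels(fDec) < 2,
         "all three factors are single-level")
  relEnd <- tr$t_end - tr$t_cue_on
  relStart <- -(tr$t_cue_on - tr$t_fixation_on)
  if (is.null(window)) window <- c(max(relStart), min(relEnd))
  starts <- seq(window[1], window[2] - binS + 1e-9, by = stepS)
  centers <- starts + binS / 2
  nB <- length(starts)
  p <- array(NA_real_, dim = c(length(units), nB, 3),
             dimnames = list(NULL, NULL, factors))
  terms_ <- list(fCue, fSmp, fDec)
  usable <- vapply(terms_, nlevels, integer(1)) >= 2
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    rel <- lapply(seq_len(nrow(tr)), function(i)
      u$spikes[[i]] - tr$t_cue_on[i])
    counts <- vapply(starts, function(st)
      vapply(rel, function(s) countInWindow(s, st, st + binS), numeric(1)),
      numeric(nrow(tr)))
    for (b in seq_len(nB)) {
      y <- counts[, b] / binS
      if (stats::sd(y) == 0) { p[ui, b, usable] <- 1; next }
      df <- data.frame(y = y, cue = fCue, smp = fSmp, dec = fDec)
      rhs <- c("cue", "smp", "dec")[usable]
      fit <- stats::lm(stats::reformulate(rhs, "y"), data = df)
      dr <- tryCatch(stats::drop1(fit, test = "F"),
                     error = function(e) NULL)
      if (is.null(dr)) { p[ui, b, usable] <- 1; next }
      pv <- dr[rhs, "Pr(>F)"]
      pv[is.na(pv)] <- 1
      p[ui, b, usable] <- pv
    }
  }
  flagged <- !is.na(p) & p < alpha
  fractions <- apply(flagged, c(2, 3), mean)
  nUnits <- length(units)
  binomP <- apply(flagged, c(2, 3), function(f)
    selectiveFractionTest(sum(f), length(f), chance = alpha)$p)
  out <- list(binCenters = centers, p = p, flagged = flagged,
              fractions = fractions, binomP = binomP, alpha = alpha,
              nUnits = nUnits)
  class(out) <- "SlidingAnovaResult"
  out
}

#' Exact two-sided binomial test of a selective fraction
#'
#' Tests whether \code{x} selective units out of \code{n} tested departs
#' from the chance rate (default 5%). Two-sided p by the minimum-likelihood
#' convention: the sum of probabilities of all outcomes no more probable
#' than the observed one.
#'
#' @param x flagged (selective) count.
#' @param n tested count (> 0).
#' @param chance chance probability (default 0.05).
#' @return list with \code{fraction} and \code{p}.
#' @export
selectiveFractionTest <- function(x, n, chance = 0.05) {
  failIf(n < 1, "need at least one tested unit")
  list(fraction = x / n,
       p = stats::binom.test(x, n, p = chance,
                             alternative = "two.sided")$p.value)
}
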