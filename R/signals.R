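## Broadband MUA event extraction, LFP preprocessing, multitaper
## time-frequency power, and band time courses.

#' Acquisition configuration
#'
#' @param thresholdMultiplier spike-detection threshold as a multiple of the
#'   RMS of the spike-band-filtered signal (default 3.5).
#' @param spikeBandHz bandpass edges for spike extraction, Hz.
#' @param lfpBandHz bandpass edges for LFP preprocessing, Hz.
#' @param lineHz mains frequency to remove, Hz.
#' @return list of class \code{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(thresholdMultiplier = 3.5,
                              spikeBandHz = c(500, 8000),
                              lfpBandHz = c(0.5, 200), lineHz = 60) {
  failIf(thresholdMultiplier <= 0, "threshold multiplier must be > 0")
  cfg <- list(thresholdMultiplier = thresholdMultiplier,
              spikeBandHz = spikeBandHz, lfpBandHz = lfpBandHz,
              lineHz = lineHz)
  class(cfg) <- "AcquisitionConfig"
  cfg
}

#' LFP analysis bands
#'
#' Alpha 8--14, beta 20--45 (the broad beta / low-gamma zone), gamma
#' 46--70 Hz.
#'
#' @return named list of length-2 edge vectors in Hz.
#' @export
lfpBands <- function() {
  list(alpha = c(8, 14), beta = c(20, 45), gamma = c(46, 70))
}

#' Threshold-crossing MUA event extraction
#'
#' Bandpass-filters the broadband trace to the spike band, then detects
#' negative-going crossings of -multiplier x RMS (RMS of the full filtered
#' trace) with a 1 ms dead time.
#'
#' @param trace numeric broadband voltage trace.
#' @param fs sampling rate, Hz.
#' @param cfg an \code{\link{acquisitionConfig}}.
#' @param deadTimeS refractory dead time between events, s (default 1e-3).
#' @return event times in seconds from trace start.
#' @export
extractMuaEvents <- function(trace, fs, cfg = acquisitionConfig(),
                             deadTimeS = 1e-3) {
  nyq <- fs / 2
  lo <- cfg$spikeBandHz[1] / nyq
  hi <- min(cfg$spikeBandHz[2], 0.95 * nyq) / nyq
  failIf(lo >= 1 || lo >= hi, "spike band infeasible at sampling rate %g", fs)
  bf <- signal::butter(3, c(lo, hi), type = "pass")
  filt <- signal::filtfilt(bf, trace)
  rms <- sqrt(mean(filt^2))
  failIf(rms == 0, "degenerate (flat) signal: RMS is zero")
  thr <- -cfg$thresholdMultiplier * rms
  below <- filt < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(crossings)) return(numeric(0))
  dead <- round(deadTimeS * fs)
  keep <- crossings[1]
  for (k in crossings[-1]) {
    if (k - keep[length(keep)] > dead) keep <- c(keep, k)
  }
  (keep - 1) / fs
}

#' Preprocess LFP traces
#'
#' Zero-phase bandpass (default 0.5--200 Hz) followed by a zero-phase notch
#' around the line frequency (58--62 Hz); electrodes flagged as variance
#' outliers are reported for exclusion from averages.
#'
#' @param traces named list (by electrode) of per-trial sample vectors.
#' @param fs sampling rate, Hz (>= 500).
#' @param cfg an \code{\link{acquisitionConfig}}.
#' @param notchHalfWidthHz half-width of the line notch, Hz (default 2).
#' @return list with \code{traces} (cleaned, same shape), \code{kept} and
#'   \code{excluded} electrode name vectors.
#' @export
preprocessLfp <- function(traces, fs, cfg = acquisitionConfig(),
                          notchHalfWidthHz = 2) {
  failIf(fs < 500, "sampling rate must be >= 500 Hz")
  nyq <- fs / 2
  hi <- min(cfg$lfpBandHz[2], 0.95 * nyq)
  bp <- signal::butter(2, c(cfg$lfpBandHz[1] / nyq, hi / nyq), type = "pass")
  notch <- NULL
  if (cfg$lineHz > 0 && cfg$lineHz < nyq) {
    notch <- signal::butter(2, c(cfg$lineHz - notchHalfWidthHz,
                                 cfg$lineHz + notchHalfWidthHz) / nyq,
                            type = "stop")
  }
  cleaned <- lapply(traces, function(trialList)
    lapply(trialList, function(x) {
      y <- signal::filtfilt(bp, x)
      if (!is.null(notch)) y <- signal::filtfilt(notch, y)
      y
    }))
  excluded <- if (length(cleaned) >= 8) flagVarianceOutliers(cleaned)
    else character(0)
  list(traces = cleaned, kept = setdiff(names(cleaned), excluded),
       excluded = excluded)
}

#' Flag electrodes with outlying variance
#'
#' Quality control for session averages: an electrode is excluded when the
#' robust z-score of its log total variance (median/MAD based) exceeds 3 in
#' absolute value, catching both noisy and dead channels.
#'
#' @param traces named list (by electrode) of per-trial sample vectors.
#' @param zCut robust z threshold (default 3).
#' @return character vector of excluded electrode names.
#' @export
flagVarianceOutliers <- function(traces, zCut = 3) {
  failIf(length(traces) < 8, "need at least 8 electrodes")
  v <- vapply(traces, function(tl) stats::var(unlist(tl)), numeric(1))
  lv <- log(pmax(v, .Machine$double.xmin))
  medv <- stats::median(lv)
  madv <- stats::mad(lv)
  if (madv == 0) madv <- 1e-12
  z <- (lv - medv) / madv
  out <- names(traces)[abs(z) > zCut]
  failIf(length(out) == length(traces), "all electrodes flagged as outliers")
  out
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' DPSS sequences computed from the classical symmetric tridiagonal
#' eigenproblem whose eigenvectors coincide with the Slepian sequences;
#' tapers are returned unit-energy, ordered by decreasing concentration.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (must satisfy k <= 2 nw - 1).
#' @return n x k matrix of tapers.
#' @export
dpssTapers <- function(n, nw = 3, k = 5) {
  failIf(k > 2 * nw - 1 + 1e-9, "k must not exceed 2*nw - 1")
  w <- nw / n
  t <- 0:(n - 1)
  diag_ <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  eig <- eigen(A, symmetric = TRUE)
  tap <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]  # sign convention
  }
  tap
}

#' Multitaper spectrogram of one trial trace
#'
#' Sliding-window multitaper power spectral density: within each window the
#' periodograms of the DPSS-tapered segments are averaged. Scaling is
#' Parseval-consistent (the one-sided PSD integrates to the signal
#' variance).
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param windowS window length, s (default 0.5).
#' @param stepS window step, s (default 0.05).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5; requires k <= 2 nw - 1).
#' @param fMax highest frequency retained, Hz (default 100).
#' @return list of class \code{SpectralPower} with \code{timeS} (window
#'   centres), \code{freqHz}, \code{power} (time x frequency, one-sided PSD
#'   in unit^2/Hz) and \code{normalization} = "raw".
#' @export
multitaperPower <- function(x, fs, windowS = 0.5, stepS = 0.05, nw = 3,
                            k = 5, fMax = 100) {
  n <- round(windowS * fs)
  failIf(n > length(x), "window longer than the trace")
  failIf(k > 2 * nw - 1 + 1e-9, "k must not exceed 2*nw - 1")
  step <- max(1L, round(stepS * fs))
  tap <- dpssTapers(n, nw, k)
  starts <- seq(1L, length(x) - n + 1L, by = step)
  freq <- (0:(n - 1)) * fs / n
  keepF <- freq <= fMax & freq <= fs / 2
  nyqBin <- freq == fs / 2 | freq == 0
  power <- matrix(0, length(starts), sum(keepF))
  for (wi in seq_along(starts)) {
    seg <- x[starts[wi]:(starts[wi] + n - 1L)]
    P <- numeric(n)
    for (j in seq_len(k)) {
      P <- P + Mod(stats::fft(seg * tap[, j]))^2
    }
    P <- P / (k * fs)
    ## fold to one-sided: double everything except DC and Nyquist
    P1 <- P
    P1[!nyqBin] <- 2 * P1[!nyqBin]
    power[wi, ] <- P1[keepF]
  }
  out <- list(timeS = (starts - 1 + n / 2) / fs, freqHz = freq[keepF],
              power = power, normalization = "raw",
              dfHz = fs / n)
  class(out) <- "SpectralPower"
  out
}

#' Baseline-normalized band power time course
#'
#' At each frequency, subtracts the mean power over the baseline (fixation)
#' window, then averages across the band's frequencies. Subtraction is
#' additive per frequency (a dB-ratio mode is available as an option).
#'
#' @param sp a \code{SpectralPower} from \code{\link{multitaperPower}}.
#' @param band length-2 band edges in Hz, or a name from
#'   \code{\link{lfpBands}}.
#' @param baselineWindowS length-2 window in trace seconds over which
#'   baseline power is estimated; must end at or before \code{cueOnS}.
#' @param cueOnS cue-onset time of the trace, s (guards against a baseline
#'   window that overlaps the stimulus).
#' @param mode "subtract" (default) or "db" (10 log10 ratio).
#' @return data.frame (time_s, value).
#' @export
bandTimecourse <- function(sp, band, baselineWindowS, cueOnS = NULL,
                           mode = c("subtract", "db")) {
  mode <- match.arg(mode)
  if (is.character(band)) band <- lfpBands()[[band]]
  failIf(is.null(band), "unknown band")
  if (!is.null(cueOnS))
    failIf(baselineWindowS[2] > cueOnS + 1e-9,
           "baseline window overlaps the cue period")
  inBase <- sp$timeS >= baselineWindowS[1] & sp$timeS <= baselineWindowS[2]
  failIf(!any(inBase), "baseline window contains no spectrogram frames")
  baseline <- colMeans(sp$power[inBase, , drop = FALSE])
  inBand <- sp$freqHz >= band[1] & sp$freqHz <= band[2]
  failIf(!any(inBand), "band contains no frequency bins")
  val <- if (mode == "subtract") {
    rowMeans(sweep(sp$power[, inBand, drop = FALSE], 2, baseline[inBand]))
  } else {
    rowMeans(10 * log10(sweep(sp$power[, inBand, drop = FALSE], 2,
                              baseline[inBand], "/")))
  }
  data.frame(time_s = sp$timeS, value = val)
}

#' Session-level band power for one epoch
#'
#' Baseline-normalized band power averaged over an epoch window, across
#' trials and kept electrodes of one session block: the session-level
#' observation used for phase comparisons.
#'
#' @param session a \linkS4class{SessionRecording} with LFP.
#' @param task task block.
#' @param band band name or edges.
#' @param cfg an \code{\link{acquisitionConfig}}.
#' @param epoch epoch over which to average (default "cue").
#' @param windowS,stepS,nw,k multitaper parameters.
#' @return single numeric value (mean normalized band power in the epoch).
#' @export
sessionBandPower <- function(session, task, band, cfg = acquisitionConfig(),
                             epoch = "cue", windowS = 0.5, stepS = 0.05,
                             nw = 3, k = 5) {
  tr <- trials(session)
  rows <- which(tr$task == task)
  failIf(length(rows) == 0, "no %s trials in session", task)
  fs <- session@lfpRateHz
  raw <- lfpTraces(session)
  failIf(length(raw) == 0, "session has no LFP")
  pre <- preprocessLfp(lapply(raw, function(tl) tl[rows]), fs, cfg)
  keep <- if (length(pre$kept)) pre$kept else names(pre$traces)
  vals <- c()
  for (el in keep) {
    for (ti in seq_along(rows)) {
      trial <- tr[rows[ti], , drop = FALSE]
      x <- pre$traces[[el]][[ti]]
      ewTrial <- epochWindow(trial, epoch)
      ## frames past the analysis epoch are never used; truncate for speed
      nMax <- min(length(x), ceiling((ewTrial[2] + windowS) * fs))
      x <- x[seq_len(nMax)]
      sp <- multitaperPower(x, fs, windowS, stepS, nw, k)
      ## keep baseline frames clear of the cue: a frame centred at t covers
      ## t +/- windowS/2
      bw <- c(trial$t_fixation_on, trial$t_cue_on - windowS / 2)
      tc <- bandTimecourse(sp, band, baselineWindowS = bw,
                           cueOnS = trial$t_cue_on)
      ew <- epochWindow(trial, epoch)
      inEp <- tc$time_s >= ew[1] & tc$time_s <= ew[2]
      if (any(inEp)) vals <- c(vals, mean(tc$value[inEp]))
    }
  }
  mean(vals)
}

#' Phase comparison of session-level band power
#'
#' One-way ANOVA of session-level epoch band power across training phases,
#' treating one session as one observation.
#'
#' @param values numeric vector of session-level band powers.
#' @param phases parallel phase labels.
#' @return list with F, df, p.
#' @export
bandPhaseAnova <- function(values, phases) {
  failIf(length(unique(phases)) < 2, "need >= 2 phases")
  ph <- factor(phases, levels = intersect(phaseLevels(), phases))
  fit <- stats::aov(values ~ ph)
  tab <- summary(fit)[[1]]
  list(F = tab["ph", "F value"],
       df = c(tab["ph", "Df"], tab["Residuals", "Df"]),
       p = tab["ph", "Pr(>F)"])
}
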