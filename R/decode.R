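## Pseudo-population decoding with cross-validation, training-set-only
## normalization, and shuffle-label nulls.

#' Decoding configuration
#'
#' @param label "location8" (8 peripheral cue locations; the centre is
#'   excluded because it never appears as a nonmatch) or "match2"
#'   (match/nonmatch status of the second stimulus).
#' @param nUnits pseudo-population size (default 200).
#' @param binS decoding bin width, s (default 0.5).
#' @param stepS bin step, s (default 0.05).
#' @param folds cross-validation folds (default 10).
#' @param repeats CV repetitions per pseudo-population (default 5).
#' @param resamples fresh pseudo-populations (default 100; together with
#'   \code{repeats} this yields \code{repeats * resamples} accuracy samples
#'   per comparison -- 500 at the defaults).
#' @param nShuffles shuffled-label resamples for the null (default 100).
#' @param alpha significance level (default 0.05).
#' @param minTrialsPerCondition trials each unit must have in every
#'   condition (default 10); units below threshold are excluded before
#'   sampling.
#' @param normalization "training" (z-score from training-fold statistics
#'   only, the default) or "all" (full-data statistics).
#' @param leakTestIntoTraining include test trials when estimating class
#'   centroids -- a deliberately broken negative control that inflates
#'   shuffled-label accuracy above chance; never use for real analyses.
#' @return list of class \code{DecodeConfig}.
#' @export
decodeConfig <- function(label = c("location8", "match2"), nUnits = 200,
                         binS = 0.5, stepS = 0.05, folds = 10, repeats = 5,
                         resamples = 100, nShuffles = 100, alpha = 0.05,
                         minTrialsPerCondition = 10,
                         normalization = c("training", "all"),
                         leakTestIntoTraining = FALSE) {
  label <- match.arg(label)
  failIf(folds < 2, "folds must be >= 2")
  if (nShuffles < 20)
    warning("nShuffles < 20: null percentile interval poorly resolved")
  cfg <- list(label = label, nUnits = as.integer(nUnits), binS = binS,
              stepS = stepS, folds = as.integer(folds),
              repeats = as.integer(repeats),
              resamples = as.integer(resamples),
              nShuffles = as.integer(nShuffles), alpha = alpha,
              minTrialsPerCondition = as.integer(minTrialsPerCondition),
              normalization = match.arg(normalization),
              leakTestIntoTraining = isTRUE(leakTestIntoTraining))
  class(cfg) <- "DecodeConfig"
  cfg
}

decodeChance <- function(label) if (label == "location8") 1 / 8 else 1 / 2

#' Per-unit binned condition rates for decoding
#'
#' Collects, for every unit of the requested task/phase blocks across
#' sessions, its per-condition trials binned on the decoding grid (bins of
#' \code{binS} advanced by \code{stepS}, clipped to the extent shared by all
#' trials, aligned to cue onset). Simultaneity is deliberately ignored:
#' pseudo-populations combine units recorded in different sessions.
#'
#' @param ds an \linkS4class{ExperimentDataset}.
#' @param task "passive" or "active".
#' @param phases phases to pool (default: all present).
#' @param cfg a \code{\link{decodeConfig}}.
#' @param correctOnly use correct trials only.
#' @return list with \code{units} (per unit: list of condition -> trials x
#'   bins rate matrices), \code{binCenters}, \code{conditions}.
#' @export
binnedConditionRates <- function(ds, task, phases = NULL,
                                 cfg = decodeConfig(), correctOnly = TRUE) {
  conds <- if (cfg$label == "location8") peripheralLocations() else c(0L, 1L)
  winStart <- -taskTiming(ds)@fixationS
  winEnd <- Inf
  pools <- list()
  for (s in sessions(ds)) {
    if (!is.null(phases) && !(s@phase %in% phases)) next
    tr <- trials(s)
    rows <- which(tr$task == task & (tr$correct | !correctOnly))
    if (!length(rows)) next
    winEnd <- min(winEnd, min(tr$t_end[rows] - tr$t_cue_on[rows]))
    condOf <- if (cfg$label == "location8") tr$cue_location[rows] else
      as.integer(tr$is_match[rows])
    for (u in spikeUnits(s)) {
      pools[[length(pools) + 1L]] <- list(
        spikes = u$spikes[rows], cond = condOf,
        cueOn = tr$t_cue_on[rows], unit_id = u$unit_id)
    }
  }
  failIf(length(pools) == 0, "no units with %s trials in requested phases",
         task)
  starts <- seq(winStart, winEnd - cfg$binS + 1e-9, by = cfg$stepS)
  failIf(length(starts) < 1, "trials too short for the decoding bin width")
  units <- lapply(pools, function(p) {
    byCond <- lapply(conds, function(cc) {
      idx <- which(p$cond == cc)
      m <- matrix(0, length(idx), length(starts))
      for (k in seq_along(idx)) {
        sp <- p$spikes[[idx[k]]] - p$cueOn[idx[k]]
        m[k, ] <- vapply(starts, function(st)
          countInWindow(sp, st, st + cfg$binS), numeric(1)) / cfg$binS
      }
      m
    })
    names(byCond) <- as.character(conds)
    byCond
  })
  ok <- vapply(units, function(u)
    all(vapply(u, nrow, integer(1)) >= cfg$minTrialsPerCondition),
    logical(1))
  failIf(!any(ok), "no unit has %d trials in every condition",
         cfg$minTrialsPerCondition)
  list(units = units[ok], binCenters = starts + cfg$binS / 2,
       conditions = conds)
}

#' Assemble one pseudo-population
#'
#' Samples \code{cfg$nUnits} units (without replacement when enough units
#' are eligible, else with replacement), draws \code{k} trials per condition
#' per unit without replacement, and randomly matches them across units to
#' form pseudo-trials.
#'
#' @param pool output of \code{\link{binnedConditionRates}}.
#' @param cfg a \code{\link{decodeConfig}}.
#' @param k trials per condition (default: the minimum available, capped at
#'   \code{cfg$minTrialsPerCondition}).
#' @return list with \code{tensor} (units x pseudo-trials x bins),
#'   \code{labels} (condition per pseudo-trial) and \code{k}.
#' @export
buildPseudopopulation <- function(pool, cfg, k = NULL) {
  nAvail <- length(pool$units)
  replace <- nAvail < cfg$nUnits
  sel <- sample.int(nAvail, cfg$nUnits, replace = replace)
  if (is.null(k)) {
    k <- min(vapply(pool$units, function(u)
      min(vapply(u, nrow, integer(1))), integer(1)))
    k <- min(k, cfg$minTrialsPerCondition)
  }
  conds <- pool$conditions
  nBins <- length(pool$binCenters)
  nPseudo <- k * length(conds)
  tensor <- array(0, dim = c(cfg$nUnits, nPseudo, nBins))
  labels <- rep(conds, each = k)
  for (ui in seq_along(sel)) {
    u <- pool$units[[sel[ui]]]
    off <- 0L
    for (cc in as.character(conds)) {
      m <- u[[cc]]
      draw <- sample.int(nrow(m), k)  # without replacement within a resample
      tensor[ui, off + seq_len(k), ] <- m[draw, , drop = FALSE]
      off <- off + k
    }
  }
  list(tensor = tensor, labels = labels, k = k)
}

## Stratified fold assignment: within each condition, trials are permuted
## and dealt to folds cyclically.
stratifiedFolds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cc in unique(labels)) {
    idx <- sample(which(labels == cc))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

## Maximum-correlation-coefficient classification of one bin.
## M: units x trials; returns accuracy over the test set.
mccBinAccuracy <- function(M, labels, fold, testFold, normalization,
                           leak = FALSE) {
  trainIdx <- which(fold != testFold)
  testIdx <- which(fold == testFold)
  if (length(testIdx) == 0) return(NA_real_)  # fold empty at small k
  if (leak) trainIdx <- seq_along(labels)  # broken on purpose
  statIdx <- if (normalization == "training") trainIdx else
    seq_along(labels)
  mu <- rowMeans(M[, statIdx, drop = FALSE])
  sd_ <- apply(M[, statIdx, drop = FALSE], 1, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) return(1 / length(unique(labels)))  # no usable feature
  Z <- (M[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  classes <- sort(unique(labels[trainIdx]))  # only trainable classes
  centroids <- vapply(classes, function(cc)
    rowMeans(Z[, trainIdx[labels[trainIdx] == cc], drop = FALSE]),
    numeric(sum(keep)))
  Zt <- Z[, testIdx, drop = FALSE]
  if (sum(keep) < 2) {
    ## a single usable feature: correlation is undefined, fall back to the
    ## nearest centroid in absolute distance
    d <- abs(outer(as.vector(Zt), as.vector(centroids), "-"))
    pred <- classes[apply(d, 1, which.min)]
  } else {
    cors <- suppressWarnings(stats::cor(Zt, centroids))
    cors[is.na(cors)] <- -Inf
    pred <- classes[max.col(cors, ties.method = "first")]
  }
  mean(pred == labels[testIdx])
}

## One full CV run on a pseudo-population; returns one accuracy sample per
## repeat, per bin (bins x repeats).
cvRun <- function(pp, cfg) {
  nBins <- dim(pp$tensor)[3]
  acc <- matrix(NA_real_, nBins, cfg$repeats)
  for (rep_ in seq_len(cfg$repeats)) {
    fold <- stratifiedFolds(pp$labels, cfg$folds)
    for (b in seq_len(nBins)) {
      a <- vapply(seq_len(cfg$folds), function(tf)
        mccBinAccuracy(pp$tensor[, , b], pp$labels, fold, tf,
                       cfg$normalization, cfg$leakTestIntoTraining),
        numeric(1))
      acc[b, rep_] <- mean(a, na.rm = TRUE)  # folds left empty at small k
    }
  }
  acc
}

#' Decode a variable over time from pseudo-populations
#'
#' For each of \code{cfg$resamples} freshly assembled pseudo-populations,
#' runs \code{cfg$repeats} rounds of stratified \code{cfg$folds}-fold
#' cross-validation in every time bin. Features are z-scored with means and
#' standard deviations computed from the training folds only; the classifier
#' is the maximum-correlation-coefficient rule (nearest class centroid by
#' Pearson correlation). Returns every accuracy sample
#' (\code{repeats * resamples} per bin).
#'
#' @param pool output of \code{\link{binnedConditionRates}}.
#' @param cfg a \code{\link{decodeConfig}}.
#' @param seed RNG seed for resampling.
#' @param shuffle permute labels within each resample before decoding
#'   (builds the null).
#' @return matrix bins x (repeats * resamples) of accuracies.
#' @export
decodeTimecourse <- function(pool, cfg, seed, shuffle = FALSE) {
  nRes <- if (shuffle) cfg$nShuffles else cfg$resamples
  withSeed(seed, {
    out <- vector("list", nRes)
    for (rs in seq_len(nRes)) {
      pp <- buildPseudopopulation(pool, cfg)
      if (shuffle) pp$labels <- sample(pp$labels)
      out[[rs]] <- cvRun(pp, cfg)
    }
    do.call(cbind, out)
  })
}

#' Shuffled-label null distribution
#'
#' Runs the identical resample/CV procedure with condition labels permuted
#' within each resample and summarizes the per-bin null 95% interval.
#'
#' @param pool output of \code{\link{binnedConditionRates}}.
#' @param cfg a \code{\link{decodeConfig}}.
#' @param seed RNG seed.
#' @return list with \code{samples} (bins x null samples) and
#'   \code{interval} (2 x bins: 2.5 and 97.5 percentiles).
#' @export
shuffleNull <- function(pool, cfg, seed) {
  samples <- decodeTimecourse(pool, cfg, seed, shuffle = TRUE)
  interval <- apply(samples, 1, stats::quantile, probs = c(0.025, 0.975))
  list(samples = samples, interval = interval)
}

#' Full decoding analysis with significance
#'
#' Convenience wrapper: actual decoding, shuffle null, and per-bin
#' significance (mean actual accuracy outside the null 95% interval; a
#' two-sided z-test p-value is reported alongside).
#'
#' @param pool output of \code{\link{binnedConditionRates}}.
#' @param cfg a \code{\link{decodeConfig}}.
#' @param seed RNG seed (the null uses a derived child seed).
#' @return a \linkS4class{DecodingResult}.
#' @export
decodeWithNull <- function(pool, cfg, seed) {
  acc <- decodeTimecourse(pool, cfg, seed)
  nul <- shuffleNull(pool, cfg, childSeed(seed, 999))
  res <- new("DecodingResult", label = cfg$label,
             binCenters = pool$binCenters, accuracy = acc,
             nullAccuracy = nul$samples, chance = decodeChance(cfg$label),
             flags = logical(nrow(acc)), nullInterval = nul$interval,
             zP = numeric(nrow(acc)))
  decodeSignificance(res)
}

#' Per-bin significance of a decoding result
#'
#' Flags bins whose mean actual accuracy lies outside the 2.5--97.5
#' percentile interval of the shuffled-label accuracies, and reports a
#' two-sided z-test p-value comparing the actual and null sample means.
#'
#' @param result a \linkS4class{DecodingResult} with null samples.
#' @return the result with \code{flags}, \code{nullInterval} and \code{zP}
#'   filled in.
#' @export
decodeSignificance <- function(result) {
  acc <- result@accuracy
  nul <- result@nullAccuracy
  failIf(ncol(nul) == 0, "no null samples present")
  interval <- apply(nul, 1, stats::quantile, probs = c(0.025, 0.975))
  m <- rowMeans(acc)
  flags <- m < interval[1, ] | m > interval[2, ]
  z <- (m - rowMeans(nul)) /
    sqrt(apply(acc, 1, stats::var) / ncol(acc) +
           apply(nul, 1, stats::var) / ncol(nul))
  zP <- 2 * stats::pnorm(-abs(z))
  zP[!is.finite(z)] <- 1
  initialize(result, flags = as.logical(flags), nullInterval = interval,
             zP = zP)
}
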