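## End-to-end orchestration: generate or load a dataset, run every stage per
## phase and task, and write a report of CSV/JSON tables.

#' Pipeline configuration
#'
#' @param synth a \code{\link{synthConfig}} (used when \code{datasetPath} is
#'   NULL).
#' @param datasetPath path to a serialized dataset to load instead of
#'   generating one.
#' @param outDir output directory for report tables.
#' @param stages character vector of stages to run; any of "screening",
#'   "psth", "heatmap", "noisecorr", "lfp", "decode", "dpca", "anova".
#' @param seed master analysis seed (mandatory when generating).
#' @param decode a \code{\link{decodeConfig}} template (its label is set per
#'   analysis); sized down by default for the report.
#' @param minPairTrials minimum trials per correlation pair.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(synth = NULL, datasetPath = NULL, outDir,
                           stages = c("screening", "psth", "heatmap",
                                      "noisecorr", "lfp", "decode", "dpca",
                                      "anova"),
                           seed = NULL,
                           decode = decodeConfig(nUnits = 50, resamples = 10,
                                                 nShuffles = 20),
                           minPairTrials = 20) {
  known <- c("screening", "psth", "heatmap", "noisecorr", "lfp", "decode",
             "dpca", "anova")
  bad <- setdiff(stages, known)
  failIf(length(bad) > 0, "unknown stage(s): %s", paste(bad, collapse = ", "))
  failIf(is.null(synth) && is.null(datasetPath),
         "either a synth config or a dataset path is required")
  failIf(is.null(datasetPath) && is.null(seed) && is.null(synth$seed),
         "a seed is mandatory for synthetic sources")
  cfg <- list(synth = synth, datasetPath = datasetPath, outDir = outDir,
              stages = stages, seed = seed %||% synth$seed, decode = decode,
              minPairTrials = minPairTrials)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a YAML pipeline configuration file
#'
#' Reads a YAML file mirroring \code{\link{pipelineConfig}} /
#' \code{\link{synthConfig}} field-for-field, resolves all defaults and
#' returns the normalized configuration, or raises an error listing every
#' problem with its field path.
#'
#' @param path YAML file.
#' @return a \code{PipelineConfig} with all defaults resolved.
#' @export
validateConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  errs <- character()
  knownTop <- c("synth", "dataset_path", "out_dir", "stages", "seed",
                "decode", "min_pair_trials")
  for (k in setdiff(names(raw), knownTop))
    errs <- c(errs, sprintf("unknown key '%s'", k))
  synth <- NULL
  if (!is.null(raw$synth)) {
    knownSynth <- c("n_units", "n_trials_per_condition", "sessions_per_phase",
                    "lfp_rate_hz", "n_lfp_electrodes", "seed", "sua_fraction",
                    "line_hz", "active_accuracy")
    for (k in setdiff(names(raw$synth), knownSynth))
      errs <- c(errs, sprintf("unknown key 'synth.%s'", k))
    if (!length(errs)) {
      synth <- tryCatch(
        synthConfig(
          nUnits = raw$synth$n_units %||% 24,
          nTrialsPerCondition = raw$synth$n_trials_per_condition %||% 6,
          sessionsPerPhase = raw$synth$sessions_per_phase %||% 3,
          lfpRateHz = raw$synth$lfp_rate_hz %||% 500,
          nLfpElectrodes = raw$synth$n_lfp_electrodes %||% 8,
          seed = raw$synth$seed %||% raw$seed,
          suaFraction = raw$synth$sua_fraction %||% 0.3,
          lineHz = raw$synth$line_hz %||% 0,
          activeAccuracy = raw$synth$active_accuracy %||% 0.85),
        error = function(e) { errs <<- c(errs, sprintf("synth: %s",
                                                       conditionMessage(e)))
                              NULL })
    }
  }
  dec <- tryCatch({
    d <- raw$decode %||% list()
    if (!is.null(d$folds) && d$folds < 2)
      stop("decode.folds: must be >= 2")
    decodeConfig(nUnits = d$n_units %||% 50, folds = d$folds %||% 10,
                 repeats = d$repeats %||% 5, resamples = d$resamples %||% 10,
                 nShuffles = d$n_shuffles %||% 20)
  }, error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  if (is.null(raw$out_dir)) errs <- c(errs, "out_dir: required")
  if (length(errs))
    stop(sprintf("invalid pipeline configuration:\n  - %s",
                 paste(errs, collapse = "\n  - ")), call. = FALSE)
  pipelineConfig(synth = synth, datasetPath = raw$dataset_path,
                 outDir = raw$out_dir,
                 stages = raw$stages %||% c("screening", "psth", "heatmap",
                                            "noisecorr", "lfp", "decode",
                                            "dpca", "anova"),
                 seed = raw$seed, decode = dec,
                 minPairTrials = raw$min_pair_trials %||% 20)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) an experiment, then per phase and task produces:
#' responsive-unit counts and fractions, population PSTHs, daily
#' best-location rate summaries, noise-correlation distance profiles with
#' the phase ANCOVA and the same-electrode phase x task ANOVA, LFP band
#' time-course summaries with the session-level phase ANOVA, decoding time
#' courses with shuffle-null bands, and dPCA variance tables. Every section
#' is written as CSV/JSON under \code{outDir}; re-running with the same
#' configuration and seed reproduces identical numerics.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisible list: the report bundle (section tables, timings, and
#'   the dataset).
#' @export
runPipeline <- function(cfg) {
  failIf(!inherits(cfg, "PipelineConfig"),
         "cfg must come from pipelineConfig()")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  ds <- if (!is.null(cfg$datasetPath)) readDataset(cfg$datasetPath)
    else generateExperiment(cfg$synth)
  report <- list(dataset = ds)
  timings <- list(dataset = proc.time()[["elapsed"]] - t0)
  stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    tS <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - tS
    report[[name]] <<- res
    res
  }
  tasksOf <- function(s) unique(trials(s)$task)

  stage("screening", {
    rows <- list()
    for (s in sessions(ds)) {
      for (task in tasksOf(s)) {
        scr <- screenSession(s, task)
        ev <- scr[scr$evaluable, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          session = sessionId(s), phase = sessionPhase(s), task = task,
          n_units = nrow(scr), n_evaluable = nrow(ev),
          n_responsive = sum(ev$is_responsive),
          responsive_fraction = mean(ev$is_responsive),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(cfg$outDir, "screening_summary.csv"),
                     row.names = FALSE)
    out
  })

  stage("psth", {
    out <- list()
    for (task in c("passive", "active")) {
      for (s in sessions(ds)) {
        tr <- trials(s)
        if (!task %in% tr$task) next
        rowsIdx <- which(tr$task == task)
        blk <- tr[rowsIdx, , drop = FALSE]
        units <- lapply(spikeUnits(s), function(u) {
          u$spikes <- u$spikes[rowsIdx]; u })
        ps <- populationPsth(units, blk, binS = 0.05,
                             baselineSubtract = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          session = sessionId(s), phase = sessionPhase(s), task = task,
          bin_center_s = ps$binCenters, mean_rate = ps$mean, sem = ps$sem,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, out)
    utils::write.csv(out, file.path(cfg$outDir, "population_psth.csv"),
                     row.names = FALSE)
    out
  })

  stage("heatmap", {
    rows <- list()
    for (s in sessions(ds)) {
      tr <- trials(s)
      for (task in tasksOf(s)) {
        rowsIdx <- which(tr$task == task & tr$correct)
        blk <- tr[rowsIdx, , drop = FALSE]
        for (epoch in c("cue", "delay1")) {
          vals <- vapply(spikeUnits(s), function(u) {
            uu <- u; uu$spikes <- u$spikes[rowsIdx]
            loc <- bestLocation(uu, blk, epoch)
            mean(epochRates(uu, blk, epoch,
                            which(blk$cue_location == loc)))
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            session = sessionId(s), phase = sessionPhase(s), task = task,
            epoch = epoch, mean_best_rate = mean(vals),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    utils::write.csv(out, file.path(cfg$outDir, "daily_best_location.csv"),
                     row.names = FALSE)
    out
  })

  stage("noisecorr", {
    out <- list(pairs = NULL, ancova = list(), sameElectrode = NULL)
    tabs <- list()
    for (task in c("passive", "active")) {
      tab <- tryCatch(experimentCorrelationTable(ds, task,
                                                 cfg$minPairTrials),
                      error = function(e) data.frame())
      if (!is.null(tab) && nrow(tab)) tabs[[task]] <- tab
    }
    allPairs <- do.call(rbind, tabs)
    out$pairs <- allPairs
    utils::write.csv(allPairs, file.path(cfg$outDir, "noisecorr_pairs.csv"),
                     row.names = FALSE)
    for (task in names(tabs)) {
      tab <- tabs[[task]]
      if (length(unique(tab$phase)) >= 2) {
        a <- phaseComparisonAncova(tab)
        out$ancova[[task]] <- list(term = "phase", F = a$F, df = a$df,
                                   p = a$p, distance_coef = a$distance_coef)
      }
    }
    if (!is.null(allPairs) && nrow(allPairs) &&
        length(unique(allPairs$task)) == 2 &&
        sum(allPairs$distance_mm == 0) >= 8 &&
        length(unique(allPairs$phase[allPairs$distance_mm == 0])) >= 2) {
      out$sameElectrode <- tryCatch(sameElectrodePhaseTaskAnova(allPairs),
                                    error = function(e) NULL)
    }
    jsonlite::write_json(out$ancova,
                         file.path(cfg$outDir, "noisecorr_ancova.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  stage("lfp", {
    rows <- list()
    for (s in sessions(ds)) {
      if (!length(lfpTraces(s))) next
      for (task in tasksOf(s)) {
        for (band in names(lfpBands())) {
          v <- sessionBandPower(s, task, band)
          rows[[length(rows) + 1L]] <- data.frame(
            session = sessionId(s), phase = sessionPhase(s), task = task,
            band = band, epoch = "cue", value = v, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    anv <- list()
    if (!is.null(out)) {
      utils::write.csv(out, file.path(cfg$outDir, "lfp_band_timecourse.csv"),
                       row.names = FALSE)
      for (task in unique(out$task)) {
        for (band in unique(out$band)) {
          sub <- out[out$task == task & out$band == band, , drop = FALSE]
          if (length(unique(sub$phase)) >= 2 && nrow(sub) > length(unique(sub$phase))) {
            a <- bandPhaseAnova(sub$value, sub$phase)
            anv[[paste(task, band, sep = "_")]] <-
              list(F = a$F, df = a$df, p = a$p)
          }
        }
      }
      jsonlite::write_json(anv, file.path(cfg$outDir, "lfp_band_anova.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(sessions = out, anova = anv)
  })

  stage("decode", {
    out <- list()
    jobs <- list(list(label = "location8", task = "passive", phases = NULL),
                 list(label = "match2", task = "passive", phases = NULL),
                 list(label = "match2", task = "active",
                      phases = c("II", "III", "IV")))
    for (j in jobs) {
      dcfg <- cfg$decode
      dcfg$label <- j$label
      pool <- tryCatch(binnedConditionRates(ds, j$task, j$phases, dcfg),
                       error = function(e) NULL)
      if (is.null(pool)) next
      res <- decodeWithNull(pool, dcfg,
                            childSeed(cfg$seed, 71, match(j$label,
                                      c("location8", "match2")),
                                      match(j$task, c("passive", "active"))))
      key <- paste(j$label, j$task, sep = "_")
      out[[key]] <- res
      utils::write.csv(data.frame(
        bin_center_s = res@binCenters, mean = rowMeans(res@accuracy),
        null_low = res@nullInterval[1, ], null_high = res@nullInterval[2, ],
        flag = res@flags, z_p = res@zP),
        file.path(cfg$outDir, sprintf("decode_%s.csv", key)),
        row.names = FALSE)
    }
    out
  })

  stage("dpca", {
    out <- list()
    for (task in c("passive", "active")) {
      tens <- tryCatch(dpcaTensor(ds, task,
                                  phases = if (task == "active")
                                    c("III", "IV") else NULL),
                       error = function(e) NULL)
      if (is.null(tens) || anyNA(tens)) next
      fit <- dpcaFit(dpcaMarginalize(tens), nComponents = 5)
      out[[task]] <- fit
      vt <- varianceTable(fit)
      vt$task <- task
      utils::write.csv(vt, file.path(cfg$outDir,
                                     sprintf("dpca_variance_%s.csv", task)),
                       row.names = FALSE)
    }
    out
  })

  stage("anova", {
    out <- list()
    for (task in c("passive", "active")) {
      pools <- list(); trTabs <- list()
      for (s in sessions(ds)) {
        tr <- trials(s)
        rowsIdx <- which(tr$task == task & tr$correct)
        if (length(rowsIdx) < 20) next
        units <- lapply(spikeUnits(s), function(u) {
          u$spikes <- u$spikes[rowsIdx]; u })
        res <- slidingThreeWayAnova(units, tr[rowsIdx, , drop = FALSE])
        pools[[length(pools) + 1L]] <- data.frame(
          session = sessionId(s), phase = sessionPhase(s), task = task,
          bin_center_s = rep(res$binCenters, times = 3),
          factor = rep(dimnames(res$p)[[3]], each = length(res$binCenters)),
          fraction = as.vector(res$fractions),
          binom_p = as.vector(res$binomP), stringsAsFactors = FALSE)
      }
      if (length(pools)) out[[task]] <- do.call(rbind, pools)
    }
    tab <- do.call(rbind, out)
    if (!is.null(tab))
      utils::write.csv(tab, file.path(cfg$outDir,
                                      "sliding_anova_fractions.csv"),
                       row.names = FALSE)
    tab
  })

  report$timings <- timings
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         config_hash = ds@configHash, timings = timings),
    file.path(cfg$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
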