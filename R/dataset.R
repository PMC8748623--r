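## Dataset module: electrode geometry and on-disk serialization.

#' Physical distance between two electrodes
#'
#' Euclidean distance on the array between two 0-based, row-major electrode
#' indices. Adjacent electrodes on the default 8 x 8 grid are 0.75 mm apart.
#'
#' @param grid a \linkS4class{GridGeometry}.
#' @param e1,e2 electrode indices (0-based, row-major); vectors recycle.
#' @return distance(s) in mm.
#' @examples
#' electrodeDistance(GridGeometry(), 0, 1)   # adjacent: 0.75
#' electrodeDistance(GridGeometry(), 0, 28)  # 3 rows, 4 cols: 3.75
#' @export
electrodeDistance <- function(grid, e1, e2) {
  n <- grid@nRows * grid@nCols
  e1 <- as.integer(e1); e2 <- as.integer(e2)
  failIf(any(is.na(e1)) || any(is.na(e2)) ||
           any(e1 < 0L) || any(e1 >= n) || any(e2 < 0L) || any(e2 >= n),
         "electrode index out of range [0, %d]", n - 1L)
  r1 <- e1 %/% grid@nCols; c1 <- e1 %% grid@nCols
  r2 <- e2 %/% grid@nCols; c2 <- e2 %% grid@nCols
  grid@pitchMm * sqrt((r1 - r2)^2 + (c1 - c2)^2)
}

## Full pairwise electrode distance matrix for a set of electrode indices.
electrodeDistanceMatrix <- function(grid, electrodes) {
  n <- length(electrodes)
  outer(seq_len(n), seq_len(n), function(i, j)
    electrodeDistance(grid, electrodes[i], electrodes[j]))
}

## ---------------------------------------------------------------------------
## Serialization. One directory per experiment:
##   manifest.json               schema version, provenance, session index
##   session_<k>/trials.csv      trial table
##   session_<k>/units.json      unit metadata + ragged spike-time lists
##   session_<k>/lfp.json        per-electrode per-trial sample vectors
## All numbers are written at full double precision; the layout is plain
## text so datasets are portable and diffable.
## ---------------------------------------------------------------------------

DATASET_SCHEMA_VERSION <- "1.0"

#' Write an experiment to disk
#'
#' Serializes an \linkS4class{ExperimentDataset} to a documented plain-text
#' directory layout (CSV trial tables, JSON spike/LFP payloads, a
#' \code{manifest.json} with provenance). \code{\link{readDataset}}
#' reconstructs an identical object.
#'
#' @param ds a validated \linkS4class{ExperimentDataset}.
#' @param path directory to create (must not exist or be empty).
#' @return the manifest, invisibly (a list).
#' @export
writeDataset <- function(ds, path) {
  validObject(ds)
  for (s in ds@sessions) validObject(s)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    failIf(!ok, "cannot create dataset directory '%s'", path)
  }
  sessionEntries <- vector("list", length(ds@sessions))
  for (i in seq_along(ds@sessions)) {
    s <- ds@sessions[[i]]
    sdir <- file.path(path, sprintf("session_%03d", s@sessionId))
    dir.create(sdir, showWarnings = FALSE)
    utils::write.csv(s@trials, file.path(sdir, "trials.csv"),
                     row.names = FALSE)
    units <- lapply(s@units, function(u) list(
      unit_id = u$unit_id, kind = u$kind, electrode = u$electrode,
      spikes = lapply(u$spikes, as.numeric)))
    jsonlite::write_json(units, file.path(sdir, "units.json"),
                         digits = NA, auto_unbox = TRUE)
    lfp <- lapply(s@lfp, function(tr) lapply(tr, as.numeric))
    jsonlite::write_json(list(rate_hz = s@lfpRateHz, traces = lfp),
                         file.path(sdir, "lfp.json"),
                         digits = NA, auto_unbox = TRUE)
    sessionEntries[[i]] <- list(
      session_id = s@sessionId, phase = s@phase, dir = basename(sdir),
      n_trials = nrow(s@trials), n_units = length(s@units),
      n_lfp_electrodes = length(s@lfp))
  }
  manifest <- list(
    schema_version = DATASET_SCHEMA_VERSION,
    seed = if (is.na(ds@seed)) NULL else ds@seed,
    config_hash = ds@configHash,
    grid = list(n_rows = ds@grid@nRows, n_cols = ds@grid@nCols,
                pitch_mm = ds@grid@pitchMm),
    timing = list(fixation_s = ds@timing@fixationS, cue_s = ds@timing@cueS,
                  sample_s = ds@timing@sampleS,
                  passive_delay_s = ds@timing@passiveDelayS,
                  active_delay_s = as.list(ds@timing@activeDelayS),
                  phase4_delay_range_s = ds@timing@phase4DelayRangeS),
    sessions = sessionEntries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read an experiment from disk
#'
#' Reads a directory written by \code{\link{writeDataset}} (or conforming to
#' the same schema), validating every invariant; malformed files raise
#' errors naming the offending file and record.
#'
#' @param path dataset directory containing \code{manifest.json}.
#' @return an \linkS4class{ExperimentDataset}.
#' @export
readDataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  failIf(!file.exists(mf), "no manifest.json under '%s'", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  for (f in c("schema_version", "grid", "timing", "sessions"))
    failIf(is.null(manifest[[f]]), "manifest.json: missing field '%s'", f)
  g <- manifest$grid
  grid <- GridGeometry(g$n_rows, g$n_cols, g$pitch_mm)
  tm <- manifest$timing
  timing <- TaskTiming(
    fixationS = tm$fixation_s, cueS = tm$cue_s, sampleS = tm$sample_s,
    passiveDelayS = tm$passive_delay_s,
    activeDelayS = unlist(tm$active_delay_s),
    phase4DelayRangeS = as.numeric(unlist(tm$phase4_delay_range_s)))
  sessions <- lapply(manifest$sessions, function(entry) {
    sdir <- file.path(path, entry$dir)
    tfile <- file.path(sdir, "trials.csv")
    failIf(!file.exists(tfile), "missing trial table '%s'", tfile)
    tr <- utils::read.csv(tfile, stringsAsFactors = FALSE)
    missing <- setdiff(trialColumns(), names(tr))
    failIf(length(missing) > 0, "%s: missing column(s) %s", tfile,
           paste(missing, collapse = ", "))
    tr$is_match <- as.logical(tr$is_match)
    tr$correct <- as.logical(tr$correct)
    tr$t_targets_on <- as.numeric(tr$t_targets_on)
    probs <- validateTrials(tr)
    failIf(length(probs) > 0, "%s: %s", tfile, probs[1])
    ufile <- file.path(sdir, "units.json")
    failIf(!file.exists(ufile), "missing units file '%s'", ufile)
    uraw <- jsonlite::read_json(ufile, simplifyVector = FALSE)
    units <- lapply(uraw, function(u) {
      for (f in c("unit_id", "kind", "electrode", "spikes"))
        failIf(is.null(u[[f]]), "%s: unit entry missing field '%s'", ufile, f)
      list(unit_id = u$unit_id, kind = u$kind,
           electrode = as.integer(u$electrode),
           spikes = lapply(u$spikes, function(s) as.numeric(unlist(s))))
    })
    lfile <- file.path(sdir, "lfp.json")
    failIf(!file.exists(lfile), "missing lfp file '%s'", lfile)
    lraw <- jsonlite::read_json(lfile, simplifyVector = FALSE)
    lfp <- lapply(lraw$traces, function(tr2)
      lapply(tr2, function(v) as.numeric(unlist(v))))
    rate <- if (length(lfp)) as.numeric(lraw$rate_hz) else
      if (!is.null(lraw$rate_hz)) as.numeric(lraw$rate_hz) else 500
    ## length check with located message before S4 validity kicks in
    for (el in names(lfp)) {
      expected <- floor(tr$t_end * rate)
      lens <- lengths(lfp[[el]])
      if (length(lens) == nrow(tr)) {
        bad <- which(abs(lens - expected) > 1)
        failIf(length(bad) > 0,
               "%s: electrode %s trial %d: LFP length %d, expected %d",
               lfile, el, tr$trial_id[bad[1]], lens[bad[1]], expected[bad[1]])
      }
    }
    SessionRecording(entry$session_id, entry$phase, tr, units, lfp, rate)
  })
  ds <- ExperimentDataset(
    sessions, grid, timing,
    seed = if (is.null(manifest$seed)) NA_integer_ else manifest$seed,
    configHash = if (is.null(manifest$config_hash)) "" else
      manifest$config_hash)
  validObject(ds)
  for (s in ds@sessions) validObject(s)
  ds
}
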