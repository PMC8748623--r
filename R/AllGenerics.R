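## Generics, accessors and show methods.

#' @rdname ExperimentDataset-class
#' @param x an object.
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))

#' @rdname ExperimentDataset-class
#' @export
setMethod("sessions", "ExperimentDataset", function(x) x@sessions)

#' @rdname ExperimentDataset-class
#' @export
setGeneric("nSessions", function(x) standardGeneric("nSessions"))

#' @rdname ExperimentDataset-class
#' @export
setMethod("nSessions", "ExperimentDataset", function(x) length(x@sessions))

#' @rdname ExperimentDataset-class
#' @export
setGeneric("arrayGeometry", function(x) standardGeneric("arrayGeometry"))

#' @rdname ExperimentDataset-class
#' @export
setMethod("arrayGeometry", "ExperimentDataset", function(x) x@grid)

#' @rdname ExperimentDataset-class
#' @export
setGeneric("taskTiming", function(x) standardGeneric("taskTiming"))

#' @rdname ExperimentDataset-class
#' @export
setMethod("taskTiming", "ExperimentDataset", function(x) x@timing)

#' @rdname SessionRecording-class
#' @param x an object.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname SessionRecording-class
#' @export
setMethod("trials", "SessionRecording", function(x) x@trials)

#' @rdname SessionRecording-class
#' @export
setGeneric("spikeUnits", function(x) standardGeneric("spikeUnits"))

#' @rdname SessionRecording-class
#' @export
setMethod("spikeUnits", "SessionRecording", function(x) x@units)

#' @rdname SessionRecording-class
#' @export
setGeneric("lfpTraces", function(x) standardGeneric("lfpTraces"))

#' @rdname SessionRecording-class
#' @export
setMethod("lfpTraces", "SessionRecording", function(x) x@lfp)

#' @rdname SessionRecording-class
#' @export
setGeneric("sessionPhase", function(x) standardGeneric("sessionPhase"))

#' @rdname SessionRecording-class
#' @export
setMethod("sessionPhase", "SessionRecording", function(x) x@phase)

#' @rdname SessionRecording-class
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname SessionRecording-class
#' @export
setMethod("sessionId", "SessionRecording", function(x) x@sessionId)

#' @rdname DecodingResult-class
#' @param x an object.
#' @export
setGeneric("accuracySamples", function(x) standardGeneric("accuracySamples"))

#' @rdname DecodingResult-class
#' @export
setMethod("accuracySamples", "DecodingResult", function(x) x@accuracy)

#' @rdname DecodingResult-class
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname DecodingResult-class
#' @export
setMethod("nullSamples", "DecodingResult", function(x) x@nullAccuracy)

#' @rdname DecodingResult-class
#' @export
setGeneric("significantBins", function(x) standardGeneric("significantBins"))

#' @rdname DecodingResult-class
#' @export
setMethod("significantBins", "DecodingResult", function(x) x@flags)

#' @rdname DpcaFit-class
#' @param x an object.
#' @export
setGeneric("varianceTable", function(x) standardGeneric("varianceTable"))

#' @rdname DpcaFit-class
#' @export
setMethod("varianceTable", "DpcaFit", function(x) x@varianceTable)

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d electrodes, %.2f mm pitch (%.2f x %.2f mm)\n",
              object@nRows, object@nCols, object@pitchMm,
              (object@nRows - 1) * object@pitchMm,
              (object@nCols - 1) * object@pitchMm))
})

setMethod("show", "SessionRecording", function(object) {
  tr <- object@trials
  cat(sprintf("SessionRecording #%d  phase %-3s  %d trials (%d passive / %d active), %d units, %d LFP electrodes\n",
              object@sessionId, object@phase, nrow(tr),
              sum(tr$task == "passive"), sum(tr$task == "active"),
              length(object@units), length(object@lfp)))
})

setMethod("show", "ExperimentDataset", function(object) {
  ph <- vapply(object@sessions, function(s) s@phase, character(1))
  cat(sprintf("ExperimentDataset: %d sessions over phases {%s}, seed %s, config %s\n",
              length(object@sessions),
              paste(unique(ph), collapse = ", "),
              ifelse(is.na(object@seed), "NA", object@seed),
              ifelse(nzchar(object@configHash), object@configHash, "<none>")))
  show(object@grid)
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %s decoding, %d bins, %d samples/bin, chance %.3f, %d/%d bins significant\n",
              object@label, nrow(object@accuracy), ncol(object@accuracy),
              object@chance, sum(object@flags), length(object@flags)))
})

setMethod("show", "DpcaFit", function(object) {
  vt <- object@varianceTable
  tot <- tapply(vt$evar_share, vt$marginalization, sum)
  cat(sprintf("DpcaFit: %d units, lambda %.3g; explained variance by marginalization: %s\n",
              object@dims[1], object@lambda,
              paste(sprintf("%s %.1f%%", names(tot), 100 * tot),
                    collapse = ", ")))
})
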