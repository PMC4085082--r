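#' @rdname EcgRecording-class
#' @param object,x an object.
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname EcgRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EcgRecording-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname EcgRecording-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname BeatSet-class
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' @rdname BeatSet-class
#' @param lead lead id, "A" or "B".
#' @export
setGeneric("beatMatrix", function(x, lead = "A") standardGeneric("beatMatrix"))

#' @rdname BeatSet-class
#' @export
setGeneric("beatInfo", function(x) standardGeneric("beatInfo"))

#' @rdname BeatSet-class
#' @export
setGeneric("dropCounts", function(x) standardGeneric("dropCounts"))

#' @rdname RandomMatrixBank-class
#' @export
setGeneric("bankMatrices", function(x) standardGeneric("bankMatrices"))

#' @rdname RandomMatrixBank-class
#' @export
setGeneric("bankSeed", function(x) standardGeneric("bankSeed"))

## ---- EcgRecording accessors ----

#' @rdname EcgRecording-class
#' @export
setMethod("recordId", "EcgRecording", function(x) x@recordId)

#' @rdname EcgRecording-class
#' @export
setMethod("samplingRate", "EcgRecording", function(x) x@samplingRate)

#' @rdname EcgRecording-class
#' @export
setMethod("annotations", "EcgRecording", function(x) x@annotations)

#' @rdname EcgRecording-class
#' @export
setMethod("signalMatrix", "EcgRecording", function(x) x@signal)

#' @rdname EcgRecording-class
#' @export
setMethod("show", "EcgRecording", function(object) {
  cat("EcgRecording", object@recordId, "\n")
  cat(sprintf("  %d samples x %d leads (%s) at %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal),
              paste(colnames(object@signal), collapse = ","),
              object@samplingRate,
              nrow(object@signal) / object@samplingRate))
  cat(sprintf("  %d annotations\n", nrow(object@annotations)))
  invisible(NULL)
})

## ---- BeatSet accessors ----

#' @rdname BeatSet-class
#' @export
setMethod("nBeats", "BeatSet", function(x) nrow(x@leadA))

#' @rdname BeatSet-class
#' @export
setMethod("beatMatrix", "BeatSet", function(x, lead = "A") {
  lead <- match.arg(lead, c("A", "B"))
  if (lead == "A") return(x@leadA)
  if (is.null(x@leadB))
    stop("this BeatSet carries no lead B windows")
  x@leadB
})

#' @rdname BeatSet-class
#' @export
setMethod("beatInfo", "BeatSet", function(x) x@beatInfo)

#' @rdname BeatSet-class
#' @export
setMethod("dropCounts", "BeatSet", function(x) x@dropCounts)

#' @rdname BeatSet-class
#' @export
setMethod("show", "BeatSet", function(object) {
  cat("BeatSet:", nBeats(object), "beats x", ncol(object@leadA),
      "samples per lead;",
      if (is.null(object@leadB)) "lead A" else "leads A,B", "\n")
  if (nBeats(object) > 0) {
    cat("  records:", paste(unique(object@beatInfo$record_id), collapse = ", "), "\n")
    print(table(object@beatInfo$aami_class))
  }
  invisible(NULL)
})

## ---- RandomMatrixBank accessors ----

#' @rdname RandomMatrixBank-class
#' @export
setMethod("bankMatrices", "RandomMatrixBank", function(x) x@matrices)

#' @rdname RandomMatrixBank-class
#' @export
setMethod("bankSeed", "RandomMatrixBank", function(x) x@seed)

#' @rdname RandomMatrixBank-class
#' @export
setMethod("show", "RandomMatrixBank", function(object) {
  cat(sprintf("RandomMatrixBank: %d Gaussian matrices of %d x %d (seed %d)\n",
              object@M, object@d, object@m, object@seed))
  invisible(NULL)
})

#' @rdname BeatEnsembleModel-class
#' @param object a BeatEnsembleModel.
#' @export
setMethod("show", "BeatEnsembleModel", function(object) {
  cat(sprintf("BeatEnsembleModel: %d RBF-SVM members, C = %g, delta = %g, lead %s\n",
              length(object@members), object@cost, object@delta, object@leadConfig))
  cat("  classes:", paste(object@classLevels, collapse = ", "), "\n")
  cat(sprintf("  bank: seed %d, %d x %d x %d\n", object@bankSeed,
              object@bankDims[1], object@bankDims[2], object@bankDims[3]))
  invisible(NULL)
})

#' @rdname HierarchicalBeatModel-class
#' @param object a HierarchicalBeatModel.
#' @export
setMethod("show", "HierarchicalBeatModel", function(object) {
  cat("HierarchicalBeatModel\n  stage 1: ")
  show(object@ensemble)
  cat(sprintf("  stage 2: SVEB if RR ratio < %.2f\n", object@rrThreshold))
  invisible(NULL)
})
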