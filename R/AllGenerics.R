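# Accessor generics and show methods for the core classes.

#' @rdname EEGRecording-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EEGRecording-class
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname EEGRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname EEGRecording-class
#' @export
setMethod("stage", "EEGRecording", function(x) x@stage)
#' @rdname EEGRecording-class
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat(sprintf("  stage: %s   subject: %s\n", object@stage, object@subjectId))
})

#' @rdname Epoch-class
#' @param x,object an \code{Epoch}.
#' @export
setMethod("eegData", "Epoch", function(x) x@data)
#' @rdname Epoch-class
#' @export
setMethod("stage", "Epoch", function(x) x@stage)
#' @rdname Epoch-class
#' @export
setMethod("show", "Epoch", function(object) {
  cat(sprintf("Epoch %d: %d channels x %d samples (stage %s, subject %s)\n",
              object@index, nrow(object@data), ncol(object@data),
              object@stage, object@subjectId))
})

#' Feature values of a FeatureMatrix
#' @rdname FeatureMatrix-class
#' @param x,object a \code{FeatureMatrix}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname FeatureMatrix-class
#' @export
setMethod("stage", "FeatureMatrix", function(x) x@stage)
#' @rdname FeatureMatrix-class
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%d channels x 5 measures), stage %s, epoch %d\n",
              nrow(object@values), object@stage, object@epochIndex))
  m <- object@values
  dimnames(m) <- list(object@channelNames, object@measureNames)
  print(round(m, 4))
})

#' @rdname GraphSample-class
#' @param object a \code{GraphSample}.
#' @export
setMethod("show", "GraphSample", function(object) {
  cat(sprintf("GraphSample: K%d complete graph, label %d (%s), subject %s\n",
              nrow(object@adjacency), object@label,
              STAGES[object@label + 1L], object@subjectId))
})

#' @rdname DatasetSplit-class
#' @param object a \code{DatasetSplit}.
#' @export
setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation / %d test (ratios %s)\n",
              length(object@train), length(object@validation),
              length(object@test),
              paste(object@ratios, collapse = "/")))
  if (length(object@featureMeans))
    cat("  features standardised with train-set statistics\n")
})

#' @rdname EvalReport-class
#' @param object an \code{EvalReport}.
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport on %d samples: accuracy %.4f\n",
              object@nSamples, object@accuracy))
  cm <- object@confusion
  dimnames(cm) <- list(true = STAGES, predicted = STAGES)
  print(cm)
  tab <- rbind(precision = object@precision, recall = object@recall,
               f1 = object@f1)
  colnames(tab) <- STAGES
  print(round(tab, 4))
})

#' @rdname GCNNModel-class
#' @param object a \code{GCNNModel}.
#' @export
setMethod("show", "GCNNModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "GCNNModel: K%d graph, Chebyshev order %d, blocks %s, FC %d -> %d, %s\n",
    cfg$nNodes, cfg$chebOrder,
    paste(cfg$blockChannels, collapse = "/"),
    cfg$flattenWidth, cfg$fcHidden,
    if (object@trained) "trained" else "untrained"))
})
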