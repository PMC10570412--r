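#' EEGRecording: a labelled multichannel EEG recording
#'
#' Holds a channels-by-samples signal matrix (microvolts), the sampling
#' rate, ordered channel names, a stage tag and a subject identifier.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one unique name per channel row.
#' @slot stage one of \code{"normal"}, \code{"acute"}, \code{"chronic"} or
#'   \code{"unknown"}.
#' @slot subjectId subject identifier string.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric",
                 channelNames = "character", stage = "character",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@data) || nrow(object@data) < 1L)
      msg <- c(msg, "data must be a numeric matrix with >= 1 channel row")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar (Hz)")
    if (length(object@channelNames) != nrow(object@data))
      msg <- c(msg, "channelNames length must equal the number of channels")
    if (anyDuplicated(object@channelNames))
      msg <- c(msg, "channel names must be unique")
    if (!(object@stage %in% c(STAGES, "unknown")))
      msg <- c(msg, "stage must be normal/acute/chronic/unknown")
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelNames channel names; defaults to [CHANNELS] when the
#'   recording has eight channels, else \code{"ch1"..."chN"}.
#' @param stage stage label, or \code{"unknown"}.
#' @param subjectId subject identifier.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2, 100), fs = 100,
#'                     channelNames = c("CA1L", "CA1R"))
#' nChannels(rec)
#' @export
EEGRecording <- function(data, fs, channelNames = NULL, stage = "unknown",
                         subjectId = "subject1") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelNames)) {
    channelNames <- if (nrow(data) == 8L) CHANNELS
                    else paste0("ch", seq_len(nrow(data)))
  }
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames), stage = stage,
      subjectId = as.character(subjectId))
}

#' Epoch: one fixed-length segment of a recording
#'
#' @slot data numeric matrix, channels x epoch samples.
#' @slot fs sampling rate in Hz.
#' @slot index 1-based ordinal position of the epoch within its recording.
#' @slot channelNames,stage,subjectId carried over from the recording.
#' @export
setClass("Epoch",
  representation(data = "matrix", fs = "numeric", index = "integer",
                 channelNames = "character", stage = "character",
                 subjectId = "character"),
  validity = function(object) {
    if (!is.numeric(object@data)) return("data must be numeric")
    if (length(object@index) != 1L || object@index < 1L)
      return("index must be a positive integer")
    TRUE
  })

#' FeatureMatrix: per-epoch complexity features (channels x 5)
#'
#' Column order is fixed to [MEASURES]: ApEn, SampEn, PE, FuzzEn, KC.
#'
#' @slot values numeric matrix, channels x 5, all finite.
#' @slot measureNames the five measure names, in column order.
#' @slot channelNames,stage,subjectId,epochIndex provenance.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", measureNames = "character",
                 channelNames = "character", stage = "character",
                 subjectId = "character", epochIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@values) != 5L)
      msg <- c(msg, "feature matrix must have exactly 5 columns")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "all feature values must be finite")
    if (!identical(object@measureNames, MEASURES))
      msg <- c(msg, "measureNames must be ApEn, SampEn, PE, FuzzEn, KC")
    if (length(msg)) msg else TRUE
  })

#' GraphSample: a complete-graph classifier input
#'
#' The adjacency is the complete graph on the channels with unit edges and
#' no self-loops; node features are the per-channel complexity values.
#' Class labels are \code{0 = normal}, \code{1 = acute}, \code{2 = chronic}.
#'
#' @slot adjacency numeric matrix, 8 x 8, symmetric, unit off-diagonal.
#' @slot nodeFeatures numeric matrix, 8 x 5, finite.
#' @slot label integer class index in 0..2.
#' @slot subjectId,epochIndex provenance.
#' @export
setClass("GraphSample",
  representation(adjacency = "matrix", nodeFeatures = "matrix",
                 label = "integer", subjectId = "character",
                 epochIndex = "integer"),
  validity = function(object) {
    msg <- character()
    A <- object@adjacency
    if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
    else {
      if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
      if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be 0")
      off <- A[row(A) != col(A)]
      if (any(off != 1)) msg <- c(msg, "off-diagonal edges must all equal 1")
    }
    if (nrow(object@nodeFeatures) != nrow(A))
      msg <- c(msg, "node count mismatch between adjacency and features")
    if (ncol(object@nodeFeatures) != 5L)
      msg <- c(msg, "node features must have 5 columns")
    if (!all(is.finite(object@nodeFeatures)))
      msg <- c(msg, "node features must be finite")
    if (!(object@label %in% 0:2)) msg <- c(msg, "label must be 0, 1 or 2")
    if (length(msg)) msg else TRUE
  })

#' DatasetSplit: train/validation/test partition of graph samples
#'
#' @slot train,validation,test lists of [GraphSample-class] objects.
#' @slot ratios the three split fractions (sum to 1).
#' @slot seed the shuffling seed.
#' @slot featureMeans,featureSds per-feature standardisation parameters,
#'   filled by [standardizeFeatures()] (length 0 until then).
#' @export
setClass("DatasetSplit",
  representation(train = "list", validation = "list", test = "list",
                 ratios = "numeric", seed = "integer",
                 featureMeans = "numeric", featureSds = "numeric"),
  validity = function(object) {
    if (length(object@ratios) != 3L ||
        abs(sum(object@ratios) - 1) > 1e-8)
      return("ratios must be three fractions summing to 1")
    TRUE
  })

#' GCNNModel: the Chebyshev graph convolutional classifier
#'
#' @slot config architecture description (node count, channel widths,
#'   Chebyshev order, pooling targets, dropout rate).
#' @slot weights named list of weight arrays.
#' @slot laplacians rescaled-Laplacian Chebyshev bases per block.
#' @slot trained logical flag; prediction requires a trained model.
#' @export
setClass("GCNNModel",
  representation(config = "list", weights = "list", laplacians = "list",
                 trained = "logical"))

#' EvalReport: multiclass classification report
#'
#' @slot confusion 3 x 3 integer matrix, rows = true, columns = predicted.
#' @slot accuracy overall accuracy as a fraction in [0, 1].
#' @slot precision,recall,f1 per-class metrics, named by stage.
#' @slot nSamples number of evaluated samples.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 nSamples = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@confusion < 0)) msg <- c(msg, "confusion counts must be >= 0")
    if (sum(object@confusion) != object@nSamples)
      msg <- c(msg, "confusion total must equal nSamples")
    if (object@nSamples > 0) {
      acc <- sum(diag(object@confusion)) / object@nSamples
      if (abs(acc - object@accuracy) > 1e-12)
        msg <- c(msg, "accuracy must equal trace/total")
    }
    if (any(object@f1 < 0 | object@f1 > 1)) msg <- c(msg, "f1 must be in [0,1]")
    if (length(msg)) msg else TRUE
  })
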