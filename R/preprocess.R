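# Epoch segmentation and fast-ripple band extraction.
#
# The band filter reconstructs the signal from only those orthonormal Haar
# wavelet detail levels whose dyadic band [fs/2^(j+1), fs/2^j] intersects
# the requested band. At fs = 1000 Hz the 250-500 Hz fast-ripple band maps
# exactly to detail level 1.

#' Band specification
#' @param low,high band edges in Hz, \code{0 < low < high <= fs/2} (checked
#'   against fs at filter time).
#' @param wavelet mother wavelet name; only \code{"haar"} is supported.
#' @export
bandSpec <- function(low = 250, high = 500, wavelet = "haar") {
  if (!identical(wavelet, "haar")) stop("only the haar wavelet is supported")
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  list(low = low, high = high, wavelet = wavelet)
}

#' Segment a recording into fixed-length epochs
#'
#' Splits the recording into non-overlapping epochs of
#' \code{epochSeconds} in temporal order; trailing samples that do not fill
#' a whole epoch are discarded. An epoch longer than the recording yields
#' an empty list.
#'
#' @param rec an [EEGRecording-class].
#' @param epochSeconds epoch length in seconds; \code{fs * epochSeconds}
#'   must be a positive integer.
#' @return A list of [Epoch-class] objects.
#' @export
segmentEpochs <- function(rec, epochSeconds = 1) {
  stopifnot(is(rec, "EEGRecording"))
  len <- rec@fs * epochSeconds
  if (abs(len - round(len)) > 1e-9 || len < 1)
    stop("fs * epochSeconds must be a positive integer")
  len <- as.integer(round(len))
  nEp <- ncol(rec@data) %/% len
  if (nEp < 1L) return(list())
  lapply(seq_len(nEp), function(i) {
    new("Epoch", data = rec@data[, ((i - 1L) * len + 1L):(i * len),
                                 drop = FALSE],
        fs = rec@fs, index = i, channelNames = rec@channelNames,
        stage = rec@stage, subjectId = rec@subjectId)
  })
}

#' Segment a recording into a fixed number of equal parts
#'
#' Used by the statistical layer (20 equal epochs per 10-min recording).
#' When the sample count is not divisible by \code{nParts} the recording is
#' truncated to the largest divisible prefix.
#'
#' @param rec an [EEGRecording-class].
#' @param nParts number of equal-length epochs (>= 1).
#' @return A list of \code{nParts} [Epoch-class] objects.
#' @export
segmentEqual <- function(rec, nParts = 20) {
  stopifnot(is(rec, "EEGRecording"))
  if (nParts < 1) stop("nParts must be >= 1")
  nParts <- as.integer(nParts)
  len <- ncol(rec@data) %/% nParts
  if (len < 1L) stop("recording shorter than the requested number of parts")
  lapply(seq_len(nParts), function(i) {
    new("Epoch", data = rec@data[, ((i - 1L) * len + 1L):(i * len),
                                 drop = FALSE],
        fs = rec@fs, index = i, channelNames = rec@channelNames,
        stage = rec@stage, subjectId = rec@subjectId)
  })
}

# one analysis step of the orthonormal Haar DWT; x may be a matrix
# (rows = channels). Odd lengths are right-padded by edge replication.
haarStep <- function(x) {
  odd <- ncol(x) %% 2L == 1L
  if (odd) x <- cbind(x, x[, ncol(x), drop = FALSE])
  ev <- x[, seq(1L, ncol(x), by = 2L), drop = FALSE]
  od <- x[, seq(2L, ncol(x), by = 2L), drop = FALSE]
  list(approx = (ev + od) / sqrt(2), detail = (ev - od) / sqrt(2),
       padded = odd)
}

haarStepInv <- function(approx, detail, padded) {
  n2 <- ncol(approx) * 2L
  out <- matrix(0, nrow(approx), n2)
  out[, seq(1L, n2, by = 2L)] <- (approx + detail) / sqrt(2)
  out[, seq(2L, n2, by = 2L)] <- (approx - detail) / sqrt(2)
  if (padded) out[, -n2, drop = FALSE] else out
}

# detail levels whose dyadic band has positive overlap with [low, high]
bandLevels <- function(fs, band) {
  if (band$high > fs / 2 + 1e-9)
    stop("band.high exceeds the Nyquist frequency fs/2")
  maxJ <- max(1L, ceiling(log2(fs / band$low) - 1))
  keep <- integer()
  for (j in seq_len(maxJ)) {
    lo <- fs / 2^(j + 1); hi <- fs / 2^j
    if (lo < band$high && hi > band$low) keep <- c(keep, j)
  }
  if (!length(keep)) stop("band intersects no dyadic detail level")
  list(keep = keep, depth = max(keep))
}

#' Haar wavelet subband filter
#'
#' Decomposes the signal with the orthonormal Haar DWT to the minimum depth
#' covering \code{band$low}, zeroes the approximation and all detail levels
#' outside the requested band, and reconstructs. Linear, same-length, and
#' removes DC exactly (constant in, zero out).
#'
#' @param x numeric vector (or channels-x-samples matrix).
#' @param fs sampling rate in Hz.
#' @param band a [bandSpec()]; at \code{fs = 1000} the default 250-500 Hz
#'   band keeps exactly detail level 1.
#' @return Filtered signal with the shape of \code{x}.
#' @export
haarBandFilter <- function(x, fs, band = bandSpec()) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 2L) stop("need at least 2 samples")
  lv <- bandLevels(fs, band)
  approx <- x
  details <- vector("list", lv$depth)
  pads <- logical(lv$depth)
  for (j in seq_len(lv$depth)) {
    st <- haarStep(approx)
    details[[j]] <- st$detail
    pads[j] <- st$padded
    approx <- st$approx
  }
  rec <- matrix(0, nrow(approx), ncol(approx))
  for (j in rev(seq_len(lv$depth))) {
    d <- if (j %in% lv$keep) details[[j]]
         else matrix(0, nrow(details[[j]]), ncol(details[[j]]))
    rec <- haarStepInv(rec, d, pads[j])
  }
  if (vec) drop(rec) else rec
}

#' Segment and band-limit a recording
#'
#' Composition of [segmentEpochs()] and [haarBandFilter()]: the recording
#' is cut into epochs first, then each epoch is filtered channel by
#' channel, keeping epochs independent of one another.
#'
#' @param rec an [EEGRecording-class].
#' @param epochSeconds epoch length in seconds.
#' @param band a [bandSpec()].
#' @return A list of band-limited [Epoch-class] objects.
#' @export
preprocessRecording <- function(rec, epochSeconds = 1, band = bandSpec()) {
  eps <- segmentEpochs(rec, epochSeconds)
  lapply(eps, function(ep) {
    ep@data <- haarBandFilter(ep@data, rec@fs, band)
    ep
  })
}
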