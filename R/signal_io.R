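# Recording input/output: delimited text (CSV) and 16-bit EDF.
#
# CSV dialect: comma-separated, '.' decimal, one header line of channel
# names, rows = samples, columns = channels. EDF files follow the European
# Data Format: a 256-byte fixed header, 256 bytes per signal header, and
# int16 little-endian data records with linear digital-to-physical scaling.

#' Read a multichannel EEG recording
#'
#' @param path file to read.
#' @param format \code{"csv"} or \code{"edf"}; guessed from the file
#'   extension when missing.
#' @param fsOverride sampling rate in Hz. Required for CSV (the format has
#'   no rate field); overrides the header rate for EDF if given.
#' @param stage,subjectId metadata attached to the recording; for EDF these
#'   default to values recovered from the recording-identification field
#'   when the file was written by [writeRecording()].
#' @return An [EEGRecording-class].
#' @export
readRecording <- function(path, format = c("csv", "edf"), fsOverride = NULL,
                          stage = NULL, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fsOverride))
      stop("CSV recordings carry no sampling rate; supply fsOverride (Hz)")
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1L)
      stop("ragged CSV: rows have differing field counts")
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    if (nrow(tab) < 1L) stop("CSV has a header but no data rows")
    EEGRecording(t(as.matrix(tab)), fs = fsOverride,
                 channelNames = colnames(tab),
                 stage = if (is.null(stage)) "unknown" else stage,
                 subjectId = if (is.null(subjectId)) "subject1" else subjectId)
  } else {
    rec <- readEDF(path)
    if (!is.null(fsOverride)) rec@fs <- as.numeric(fsOverride)
    if (!is.null(stage)) rec@stage <- assertStage(stage, allowUnknown = TRUE)
    if (!is.null(subjectId)) rec@subjectId <- subjectId
    validObject(rec)
    rec
  }
}

#' Write a multichannel EEG recording
#'
#' CSV output is lossless to printed precision; EDF quantises each channel
#' onto the 16-bit digital range mapped to the physical range
#' \code{[-physMax, physMax]}, so the round-trip error is bounded by half a
#' quantisation step (\code{2 * physMax / 65535}).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @param format \code{"csv"} or \code{"edf"}.
#' @param physMax physical range half-width for EDF output, in microvolts.
#'   Channels exceeding it widen the range automatically.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("csv", "edf"),
                           physMax = 5000) {
  stopifnot(is(rec, "EEGRecording"))
  validObject(rec)
  if (ncol(rec@data) < 1L) stop("recording has no samples")
  format <- match.arg(format)
  if (format == "csv") {
    tab <- as.data.frame(t(rec@data))
    colnames(tab) <- rec@channelNames
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    writeEDF(rec, path, physMax = physMax)
  }
  invisible(path)
}

# ---- EDF internals ---------------------------------------------------------

edfField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

writeEDF <- function(rec, path, physMax = 5000) {
  x <- rec@data
  nc <- nrow(x); n <- ncol(x); fs <- rec@fs
  # one data record per second when sample count allows, else one record
  if (fs == round(fs) && n %% fs == 0) {
    recDur <- 1; perRec <- as.integer(fs); nRec <- as.integer(n / fs)
  } else {
    recDur <- n / fs; perRec <- as.integer(n); nRec <- 1L
  }
  pmax <- max(physMax, max(abs(x)) * 1.0000001)
  pmin <- -pmax
  dmin <- -32768; dmax <- 32767
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * nc
  writeChar(paste0(
    edfField("0", 8),
    edfField("X X X X", 80),
    edfField(sprintf("subject=%s stage=%s", rec@subjectId, rec@stage), 80),
    edfField("01.01.00", 8), edfField("00.00.00", 8),
    edfField(hdrBytes, 8), edfField("", 44),
    edfField(nRec, 8), edfField(format(recDur, digits = 10), 8),
    edfField(nc, 4)), con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, edfField, "", width = width),
                    collapse = ""), con, eos = NULL)
  fld(rec@channelNames, 16)
  fld(rep("", nc), 80)                      # transducer
  fld(rep("uV", nc), 8)                     # physical dimension
  fld(rep(format(pmin, digits = 7), nc), 8)
  fld(rep(format(pmax, digits = 7), nc), 8)
  fld(rep(dmin, nc), 8)
  fld(rep(dmax, nc), 8)
  fld(rep("", nc), 80)                      # prefiltering
  fld(rep(perRec, nc), 8)
  fld(rep("", nc), 32)
  for (rr in seq_len(nRec)) {
    idx <- ((rr - 1L) * perRec + 1L):(rr * perRec)
    for (ch in seq_len(nc))
      writeBin(dig[ch, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                        # version
  rd(80)                       # patient id
  recId <- rd(80)
  rd(8); rd(8)                 # date, time
  as.integer(rd(8))            # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  pminv <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmaxv <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dminv <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmaxv <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)
  perRec <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)

  n <- perRec[1L] * nRec
  x <- matrix(0, nc, n)
  for (rr in seq_len(nRec)) {
    for (ch in seq_len(nc)) {
      d <- readBin(con, "integer", n = perRec[ch], size = 2L,
                   endian = "little", signed = TRUE)
      phys <- (d - dminv[ch]) / (dmaxv[ch] - dminv[ch]) *
        (pmaxv[ch] - pminv[ch]) + pminv[ch]
      x[ch, ((rr - 1L) * perRec[ch] + 1L):(rr * perRec[ch])] <- phys
    }
  }
  stage <- "unknown"; subj <- "subject1"
  m <- regmatches(recId, regexec("subject=(\\S+) stage=(\\S+)", recId))[[1L]]
  if (length(m) == 3L) { subj <- m[2L]; stage <- m[3L] }
  EEGRecording(x, fs = perRec[1L] / recDur, channelNames = labels,
               stage = stage, subjectId = subj)
}
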