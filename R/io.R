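#' Read a multichannel recording from disk
#'
#' Two formats are supported: \code{"edf"} (European Data Format,
#' continuous signals, via the built-in minimal reader) and
#' \code{"delimited_matrix"} (UTF-8 comma- or tab-separated text, header
#' row of channel names, one row per sample, one column per channel;
#' sampling rate must be supplied because the text format carries none).
#' When \code{montage} is given, the file's channels are checked against it
#' and any mismatch is reported by electrode name.
#'
#' @param path file path.
#' @param format "edf" or "delimited_matrix".
#' @param samplingRate required for delimited_matrix; ignored for EDF
#'   (taken from the header).
#' @param montage optional expected channel labels, in order.
#' @param subjectId,groupLabel metadata attached to the recording.
#' @return an \linkS4class{EEGRecording} with channel order as in the file.
#' @export
readRecording <- function(path, format = c("edf", "delimited_matrix"),
                          samplingRate = NULL, montage = NULL,
                          subjectId = basename(path),
                          groupLabel = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- if (format == "edf") {
    readEDF(path, subjectId, groupLabel)
  } else {
    if (is.null(samplingRate))
      stop("delimited_matrix requires a declared samplingRate")
    tab <- utils::read.table(path, header = TRUE, sep = "",
                             check.names = FALSE)
    if (!nrow(tab)) stop("no samples in ", path)
    EEGRecording(t(as.matrix(tab)), colnames(tab), samplingRate,
                 subjectId, groupLabel)
  }
  if (!is.null(montage)) {
    miss <- setdiff(montage, rec@channelNames)
    extra <- setdiff(rec@channelNames, montage)
    if (length(miss) || length(extra))
      stop("montage mismatch in ", path,
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
    ord <- match(montage, rec@channelNames)
    rec <- EEGRecording(rec@data[ord, , drop = FALSE], montage,
                        rec@samplingRate, rec@subjectId, rec@groupLabel)
  }
  validObject(rec)
  rec
}

#' Write a recording as a delimited matrix
#'
#' Header row of channel names; one row per sample, tab-separated. The
#' sampling rate is not stored in this format and must travel in a config
#' or manifest.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output path.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  tab <- as.data.frame(t(rec@data))
  names(tab) <- rec@channelNames
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## ---- minimal EDF support ------------------------------------------------
## Continuous EDF with equal per-signal rates; 16-bit little-endian samples.

readChars <- function(con, n) {
  raw <- readBin(con, "raw", n)
  trimws(rawToChar(raw))
}

readEDF <- function(path, subjectId = basename(path),
                    groupLabel = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChars(con, 8L)                       # version
  readChars(con, 80L); readChars(con, 80L) # patient, recording id
  readChars(con, 8L); readChars(con, 8L)   # start date, time
  readChars(con, 8L)                       # header byte count
  readChars(con, 44L)                      # reserved
  nRecords <- as.integer(readChars(con, 8L))
  recDur <- as.numeric(readChars(con, 8L))
  ns <- as.integer(readChars(con, 4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) readChars(con, 16L), "")
  for (i in seq_len(ns)) readChars(con, 80L)            # transducer
  for (i in seq_len(ns)) readChars(con, 8L)             # physical dim
  physMin <- vapply(seq_len(ns), function(i) as.numeric(readChars(con, 8L)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(readChars(con, 8L)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(readChars(con, 8L)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(readChars(con, 8L)), 0)
  for (i in seq_len(ns)) readChars(con, 80L)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(readChars(con, 8L)), 0L)
  for (i in seq_len(ns)) readChars(con, 32L)            # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals with unequal sampling rates are not supported")
  fs <- spr[1L] / recDur
  data <- matrix(0, ns, nRecords * spr[1L])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      data[s, cols] <- (dig - digMin[s]) * scale[s] + physMin[s]
    }
  }
  EEGRecording(data, labels, fs, subjectId, groupLabel)
}

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording as a minimal EDF file
#'
#' Continuous EDF with one-second data records and 16-bit samples, mainly
#' for interoperability checks and fixture generation; physical range is
#' taken from the data.
#'
#' @param rec an \linkS4class{EEGRecording}; samplingRate must be a whole
#'   number and the sample count a whole number of seconds.
#' @param path output path.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@samplingRate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec@data)
  if (n %% fs != 0L) stop("EDF writer needs a whole number of seconds")
  ns <- nrow(rec@data)
  nRec <- n %/% fs
  physMin <- floor(apply(rec@data, 1L, min))
  physMax <- ceiling(apply(rec@data, 1L, max))
  physMax[physMax <= physMin] <- physMin[physMax <= physMin] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(padField(x, width)), con)
  wr("0", 8L); wr("synthetic", 80L); wr("synthetic", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(as.character(256L + ns * 256L), 8L)
  wr("", 44L); wr(as.character(nRec), 8L); wr("1", 8L)
  wr(as.character(ns), 4L)
  for (i in seq_len(ns)) wr(rec@channelNames[i], 16L)
  for (i in seq_len(ns)) wr("synthetic", 80L)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (i in seq_len(ns)) wr(as.character(physMin[i]), 8L)
  for (i in seq_len(ns)) wr(as.character(physMax[i]), 8L)
  for (i in seq_len(ns)) wr("-32768", 8L)
  for (i in seq_len(ns)) wr("32767", 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(as.character(fs), 8L)
  for (i in seq_len(ns)) wr("", 32L)
  scale <- (physMax - physMin) / 65535
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((rec@data[s, cols] - physMin[s]) / scale[s]) - 32768
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

## ---- connectivity & table serialisation ---------------------------------

#' Write a connectivity matrix as delimited text
#'
#' Square matrix with a channel-name header row and column.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param path output path.
#' @export
writeConnectivity <- function(m, path) {
  stopifnot(is(m, "ConnectivityMatrix"))
  utils::write.table(m@values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a connectivity matrix written by \code{writeConnectivity}
#'
#' @param path file path.
#' @param band,epochIndex metadata to attach.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
readConnectivity <- function(path, band = "broadband", epochIndex = "mean") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  ConnectivityMatrix(as.matrix(tab), colnames(tab), band, epochIndex)
}

#' Export a weighted network as an edge list
#'
#' Delimited text with columns node_i, node_j, weight.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "WeightedNetwork"))
  e <- net@edges
  tab <- data.frame(node_i = net@nodes[e$i], node_j = net@nodes[e$j],
                    weight = e$weight)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
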