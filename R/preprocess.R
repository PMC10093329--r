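#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass of the given design
#' order, applied forward and backward (\code{signal::filtfilt}) so that the
#' net phase shift is zero. Phase-lag connectivity depends on inter-channel
#' phase relations, and a causal filter would impose identical
#' frequency-dependent lags on all channels; zero-phase application removes
#' the distortion entirely. The effective magnitude response is the square
#' of the stated design order.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param lowHz,highHz band edges in Hz, 0 < lowHz < highHz < Nyquist.
#' @param order Butterworth design order (default 4).
#' @return a filtered \linkS4class{EEGRecording} of identical shape and rate.
#' @export
bandpassFilter <- function(rec, lowHz, highHz, order = 4L) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@samplingRate
  nyq <- fs / 2
  if (!(lowHz > 0 && lowHz < highHz))
    stop("band edges must satisfy 0 < lowHz < highHz")
  if (highHz >= nyq)
    stop(sprintf("highHz = %g is at or above the Nyquist frequency %g Hz", highHz, nyq))
  n <- ncol(rec@data)
  minLen <- 3 * order * fs / lowHz
  if (n < minLen)
    stop(sprintf("signal too short for stable filtering: %d samples, need >= %.0f", n, minLen))
  flt <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  out <- t(apply(rec@data, 1L, function(ch) signal::filtfilt(flt, ch)))
  EEGRecording(out, rec@channelNames, fs, rec@subjectId, rec@groupLabel)
}

# same filter applied to a bare channels x samples matrix (epoch-level use)
filterMatrix <- function(m, fs, lowHz, highHz, order = 4L) {
  nyq <- fs / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop("band edges must lie strictly inside (0, Nyquist)")
  flt <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  t(apply(m, 1L, function(ch) signal::filtfilt(flt, ch)))
}

#' Integer-factor downsampling
#'
#' Decimates each channel by keeping every k-th sample, where k =
#' samplingRate / targetRateHz must be an integer. Anti-alias protection is
#' the caller's responsibility: in the standard pipeline the broadband
#' 4-30 Hz filter precedes decimation to 125 Hz (Nyquist 62.5 Hz), so the
#' band limit already guards the target Nyquist.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param targetRateHz target sampling rate; must divide the current rate.
#' @return the decimated \linkS4class{EEGRecording}.
#' @export
downsample <- function(rec, targetRateHz) {
  stopifnot(is(rec, "EEGRecording"), targetRateHz > 0)
  factor <- rec@samplingRate / targetRateHz
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf(paste0("downsampling from %g to %g Hz needs factor %.3g; ",
                        "only integer-factor decimation is supported ",
                        "(resample-by-ratio is not)"),
         rec@samplingRate, targetRateHz, factor))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  idx <- seq(1L, ncol(rec@data), by = factor)
  EEGRecording(rec@data[, idx, drop = FALSE], rec@channelNames, targetRateHz,
               rec@subjectId, rec@groupLabel)
}

#' Segment a recording into fixed-length overlapping epochs
#'
#' Cuts windows of \code{windowSeconds} advancing by
#' \code{window * (1 - overlapFraction)}; a trailing partial window is
#' discarded. The epoch count is
#' \code{floor((N - window_samples) / step_samples) + 1}.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param windowSeconds window length in seconds (default 4).
#' @param overlapFraction fractional overlap in [0, 1) (default 0.5).
#' @return an \linkS4class{EpochSet} (band = "broadband").
#' @export
segmentEpochs <- function(rec, windowSeconds = 4, overlapFraction = 0.5) {
  stopifnot(is(rec, "EEGRecording"))
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must lie in [0, 1)")
  fs <- rec@samplingRate
  win <- windowSeconds * fs
  if (abs(win - round(win)) > 1e-9)
    stop("windowSeconds * samplingRate must be a whole number of samples")
  win <- as.integer(round(win))
  step <- as.integer(round(win * (1 - overlapFraction)))
  if (step < 1L) stop("overlap too large: step below one sample")
  n <- ncol(rec@data)
  if (n < win)
    stop(sprintf("recording (%d samples) shorter than one %d-sample window", n, win))
  nEp <- (n - win) %/% step + 1L
  starts <- (seq_len(nEp) - 1L) * step + 1L
  epochs <- lapply(starts, function(s) rec@data[, s:(s + win - 1L), drop = FALSE])
  new("EpochSet", epochs = epochs, windowSeconds = windowSeconds,
      overlapFraction = overlapFraction, band = "broadband",
      channelNames = rec@channelNames, samplingRate = fs,
      subjectId = rec@subjectId, groupLabel = rec@groupLabel)
}

#' Separate epochs into EEG rhythms
#'
#' Applies the same zero-phase Butterworth design per band to every epoch,
#' returning one EpochSet per rhythm. Shapes and epoch counts are preserved.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param bands named list of c(low_hz, high_hz) vectors; default
#'   \code{rhythmBands()}.
#' @param order Butterworth design order (default 4).
#' @return named list of \linkS4class{EpochSet}, one per band.
#' @export
extractRhythms <- function(epochs, bands = rhythmBands(), order = 4L) {
  stopifnot(is(epochs, "EpochSet"))
  if (!length(bands)) return(list())
  fs <- epochs@samplingRate
  out <- lapply(seq_along(bands), function(b) {
    band <- checkBand(bands[[b]])
    filt <- lapply(epochs@epochs, filterMatrix, fs = fs,
                   lowHz = band[1], highHz = band[2], order = order)
    new("EpochSet", epochs = filt, windowSeconds = epochs@windowSeconds,
        overlapFraction = epochs@overlapFraction, band = names(bands)[b],
        channelNames = epochs@channelNames, samplingRate = fs,
        subjectId = epochs@subjectId, groupLabel = epochs@groupLabel)
  })
  names(out) <- names(bands)
  out
}

#' Artifact-removal hook
#'
#' Placeholder stage where ICA-based ocular/ECG/EMG artifact removal would
#' run on real recordings. Synthetic cohorts are artifact-free and component
#' selection on real data is analyst-dependent, so the default is the
#' identity; supply \code{fun} to plug in a cleaner.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param fun optional function EEGRecording -> EEGRecording.
#' @return the (possibly cleaned) recording.
#' @export
removeArtifacts <- function(rec, fun = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (is.null(fun)) rec else fun(rec)
}
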