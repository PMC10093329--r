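#' Hilbert instantaneous phase of a narrowband signal
#'
#' Computes the argument of the analytic signal \eqn{x(t) + i H[x](t)},
#' where the Hilbert transform is evaluated by zeroing negative frequencies
#' of the discrete Fourier transform. Instantaneous phase is only physically
#' meaningful for band-limited input; the caller is expected to have
#' band-pass filtered the signal first.
#'
#' @param x real numeric vector, length >= 64.
#' @return numeric vector of phases in (-pi, pi], same length as \code{x}.
#' @export
instantaneousPhase <- function(x) {
  if (!is.numeric(x) || length(x) < 64L)
    stop("signal must be a numeric vector of at least 64 samples")
  if (all(x == 0)) stop("instantaneous phase undefined for an all-zero signal")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  Arg(z)
}

#' Circular phase difference of two phase series
#'
#' Element-wise \eqn{\Delta\phi(t) = \arg e^{i(\phi_1 - \phi_2)}}, wrapped
#' to (-pi, pi].
#'
#' @param p1,p2 equal-length numeric phase vectors (radians).
#' @return numeric vector of wrapped differences.
#' @export
phaseDifference <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop(sprintf("phase series lengths differ: %d vs %d", length(p1), length(p2)))
  wrapPhase(p1 - p2)
}

#' Phase Lag Index of a phase-difference series
#'
#' \eqn{PLI = | \langle sign(\Delta\phi(t)) \rangle |}: the absolute
#' time-average of the sign of the wrapped phase difference. PLI lies in
#' [0, 1]; 0 means a phase-difference distribution symmetric around zero
#' (including exact zero lag, as produced by volume conduction), 1 means a
#' consistently one-sided lag. \code{sign(0)} contributes 0, so identical
#' signals give exactly 0.
#'
#' @param deltaPhi non-empty numeric vector of wrapped phase differences.
#' @return scalar PLI in [0, 1].
#' @export
pli <- function(deltaPhi) {
  if (!length(deltaPhi)) stop("empty phase-difference vector")
  abs(mean(sign(deltaPhi)))
}

# trim a fraction of samples from each end (Hilbert edge-effect guard)
trimEnds <- function(x, fraction) {
  k <- floor(length(x) * fraction)
  if (2L * k >= length(x)) stop("edge trim leaves no samples")
  if (k == 0L) x else x[(k + 1L):(length(x) - k)]
}

#' PLI connectivity matrix of one epoch
#'
#' Computes Hilbert instantaneous phase per channel, then for every
#' unordered channel pair the PLI of the wrapped phase-difference series
#' after trimming a fraction of samples from each end (analytic-signal
#' estimates are unreliable at window edges).
#'
#' @param epoch channels x samples numeric matrix.
#' @param channelNames electrode labels, one per row.
#' @param band band name recorded in the result (default "broadband").
#' @param epochIndex epoch identifier recorded in the result.
#' @param edgeTrimFraction fraction trimmed per end before averaging
#'   (default 0.1).
#' @return a \linkS4class{ConnectivityMatrix}; symmetric, zero diagonal,
#'   \eqn{N(N-1)/2} distinct pair values.
#' @export
pliMatrix <- function(epoch, channelNames = rownames(epoch),
                      band = "broadband", epochIndex = "1",
                      edgeTrimFraction = 0.1) {
  epoch <- as.matrix(epoch)
  nch <- nrow(epoch)
  if (nch < 2L) stop("need at least 2 channels")
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nch))
  ns <- ncol(epoch)
  kept <- ns - 2L * floor(ns * edgeTrimFraction)
  if (kept < 64L)
    stop("epoch too short: fewer than 64 samples retained after edge trimming")
  const <- apply(epoch, 1L, function(ch) all(ch == ch[1L]))
  if (any(const))
    stop("degenerate (constant) channel: ", channelNames[which(const)[1L]])
  phases <- t(apply(epoch, 1L, instantaneousPhase))
  v <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      dphi <- trimEnds(phaseDifference(phases[i, ], phases[j, ]), edgeTrimFraction)
      v[i, j] <- v[j, i] <- pli(dphi)
    }
  }
  ConnectivityMatrix(v, channelNames, band, as.character(epochIndex))
}

#' PLI matrices for every epoch of an EpochSet
#'
#' @param epochs an \linkS4class{EpochSet} (typically one rhythm band).
#' @param edgeTrimFraction per-end trim fraction (default 0.1).
#' @return list of \linkS4class{ConnectivityMatrix}, one per epoch.
#' @export
epochConnectivity <- function(epochs, edgeTrimFraction = 0.1) {
  stopifnot(is(epochs, "EpochSet"))
  lapply(seq_len(nEpochs(epochs)), function(i)
    pliMatrix(epochs@epochs[[i]], epochs@channelNames, epochs@band,
              epochIndex = i, edgeTrimFraction = edgeTrimFraction))
}

#' Average a list of connectivity matrices
#'
#' Entry-wise mean across epochs, e.g. for a subject-level matrix.
#'
#' @param mats non-empty list of \linkS4class{ConnectivityMatrix} sharing
#'   montage and band.
#' @return a \linkS4class{ConnectivityMatrix} with epochIndex "mean".
#' @export
meanConnectivity <- function(mats) {
  stopifnot(length(mats) >= 1L)
  ch <- mats[[1L]]@channelNames
  for (m in mats)
    if (!identical(m@channelNames, ch)) stop("montage mismatch across matrices")
  v <- Reduce(`+`, lapply(mats, connectivityValues)) / length(mats)
  ConnectivityMatrix(v, ch, mats[[1L]]@band, "mean")
}
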