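## Synthetic EEG cohorts with known phase-lag coupling.
##
## Ground truth for the PLI pipeline: narrowband carriers with slow
## frequency drift, pairwise phase locking with a fixed lag plus von Mises
## phase jitter, additive white noise, and two groups whose coupling
## differs on a planted edge set.

# narrowband carrier phase: the instantaneous-frequency deviation follows a
# mean-reverting AR(1) (stationary sd driftSd Hz, ~2 s relaxation) with a
# smooth tanh saturation at 80% of the band half-width, so independent
# carriers drift slowly but never pin to a common boundary frequency;
# driftSd = 0 gives a pure sinusoid.
carrierPhase <- function(n, fs, centerHz, halfWidthHz = 0, driftSd = 0) {
  if (driftSd > 0 && halfWidthHz > 0) {
    phi <- exp(-1 / (2 * fs))               # 2 s relaxation time
    innov <- rnorm(n, sd = driftSd * sqrt(1 - phi^2))
    dev <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    cap <- 0.8 * halfWidthHz
    dev <- cap * tanh(dev / cap)
  } else dev <- numeric(n)
  f <- centerHz + dev
  cumsum(2 * pi * f / fs) + runif(1, -pi, pi)
}

# blockwise von Mises phase jitter: constant within blocks so the signal
# stays locally narrowband (Hilbert phase tracks it), iid across blocks so
# the marginal jitter law is exactly von Mises(0, kappa).
blockJitter <- function(n, fs, kappa, blockSeconds = 0.25) {
  if (!is.finite(kappa)) return(numeric(n))
  bs <- max(1L, as.integer(round(blockSeconds * fs)))
  nb <- ceiling(n / bs)
  rep(rvonmises(nb, 0, kappa), each = bs)[seq_len(n)]
}

#' Generate a phase-locked pair of narrowband signals
#'
#' Channel 1 is a narrowband oscillation at \code{centerHz} (with optional
#' slow random frequency drift); channel 2's instantaneous phase equals
#' channel 1's plus \code{lag} plus von Mises jitter of the stated
#' concentration (kappa = Inf means no jitter, kappa = 0 uniform jitter).
#' Jitter is held constant over short blocks (default 0.25 s) so both
#' channels remain locally narrowband while the marginal jitter
#' distribution is exactly von Mises. Optional independent white noise is
#' added to both channels.
#'
#' @param nSamples number of samples (>= 256).
#' @param samplingRate Hz.
#' @param centerHz carrier frequency, 0 < centerHz < samplingRate/2.
#' @param lag phase lag in radians, in (-pi, pi].
#' @param concentration von Mises kappa >= 0 (Inf = perfect locking).
#' @param seed integer seed.
#' @param amplitude oscillation amplitude (default 1).
#' @param noiseSd additive white-noise sd (default 0).
#' @param driftSd stationary sd of the slow frequency drift in Hz
#'   (default 0 = pure sinusoid).
#' @param halfWidthHz drift bound around the carrier (default 1).
#' @param jitterBlockSeconds jitter coherence block (default 0.25 s).
#' @return list with numeric vectors \code{x1}, \code{x2}.
#' @export
generatePhaseLockedPair <- function(nSamples, samplingRate, centerHz, lag,
                                    concentration, seed, amplitude = 1,
                                    noiseSd = 0, driftSd = 0, halfWidthHz = 1,
                                    jitterBlockSeconds = 0.25) {
  if (nSamples < 256L) stop("need at least 256 samples")
  if (!(centerHz > 0 && centerHz < samplingRate / 2))
    stop("centerHz must lie strictly inside (0, Nyquist)")
  withSeed(seed, {
    p1 <- carrierPhase(nSamples, samplingRate, centerHz, halfWidthHz, driftSd)
    jit <- blockJitter(nSamples, samplingRate, concentration, jitterBlockSeconds)
    p2 <- p1 + lag + jit
    x1 <- amplitude * cos(p1)
    x2 <- amplitude * cos(p2)
    if (noiseSd > 0) {
      x1 <- x1 + rnorm(nSamples, sd = noiseSd)
      x2 <- x2 + rnorm(nSamples, sd = noiseSd)
    }
    list(x1 = x1, x2 = x2)
  })
}

#' Specify phase coupling for one rhythm band
#'
#' @param band c(low_hz, high_hz) of the rhythm.
#' @param edges data.frame with columns from, to (electrode labels), lag
#'   (radians, nonzero for a PLI-visible coupling) and concentration (von
#'   Mises kappa); may have zero rows.
#' @param backgroundNoiseSd white-noise sd this band spec contributes.
#' @param oscillationAmplitude amplitude of this band's oscillations.
#' @return a validated coupling-spec list.
#' @export
couplingSpec <- function(band, edges = NULL, backgroundNoiseSd = 0.5,
                         oscillationAmplitude = 1) {
  checkBand(band)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        lag = numeric(0), concentration = numeric(0))
  stopifnot(all(c("from", "to", "lag", "concentration") %in% names(edges)))
  if (nrow(edges) && any(edges$from == edges$to))
    stop("self-coupling is not allowed")
  if (backgroundNoiseSd <= 0) stop("backgroundNoiseSd must be positive")
  if (oscillationAmplitude <= 0) stop("oscillationAmplitude must be positive")
  list(band = band, edges = edges, backgroundNoiseSd = backgroundNoiseSd,
       oscillationAmplitude = oscillationAmplitude)
}

#' Specify a two-group synthetic cohort
#'
#' Both groups share montage, duration and sampling rate; per-subject seeds
#' derive deterministically from \code{masterSeed}, so the whole cohort is
#' a pure function of the spec.
#'
#' @param nSubjectsPerGroup named integer vector c(LGAD = ., HGAD = .) or a
#'   single integer used for both groups. Default c(LGAD = 30, HGAD = 21),
#'   the cohort sizes of the clinical study the pipeline emulates.
#' @param durationSeconds recording length (default 444 s, about 220
#'   four-second 50\%-overlap epochs per subject after downsampling).
#' @param samplingRate acquisition rate in Hz (default 250).
#' @param montage electrode labels (default \code{canonicalMontage()}).
#' @param groupSpecs named list (LGAD, HGAD) of lists of
#'   \code{\link{couplingSpec}}; default \code{defaultGroupSpecs()}.
#' @param masterSeed integer master seed (default 20230413).
#' @param driftSd stationary sd of the slow carrier-frequency drift in Hz
#'   (default 0.3).
#' @return a validated cohort-spec list.
#' @export
cohortSpec <- function(nSubjectsPerGroup = c(LGAD = 30L, HGAD = 21L),
                       durationSeconds = 444, samplingRate = 250,
                       montage = canonicalMontage(),
                       groupSpecs = defaultGroupSpecs(),
                       masterSeed = 20230413L, driftSd = 0.3) {
  if (length(nSubjectsPerGroup) == 1L)
    nSubjectsPerGroup <- c(LGAD = nSubjectsPerGroup, HGAD = nSubjectsPerGroup)
  nSubjectsPerGroup <- nSubjectsPerGroup[c("LGAD", "HGAD")]
  stopifnot(!anyNA(nSubjectsPerGroup), all(nSubjectsPerGroup >= 1),
            durationSeconds > 0, samplingRate > 0,
            all(c("LGAD", "HGAD") %in% names(groupSpecs)))
  for (g in c("LGAD", "HGAD"))
    for (cs in groupSpecs[[g]]) {
      bad <- setdiff(c(cs$edges$from, cs$edges$to), montage)
      if (length(bad))
        stop("coupling edge names channel outside montage: ",
             paste(bad, collapse = ", "))
    }
  list(nSubjectsPerGroup = nSubjectsPerGroup,
       durationSeconds = durationSeconds, samplingRate = samplingRate,
       montage = montage, groupSpecs = groupSpecs,
       masterSeed = as.integer(masterSeed), driftSd = driftSd)
}

#' Default planted two-group coupling scenario
#'
#' Mirrors the direction (not the magnitude) of the anxiety-severity
#' finding the pipeline was built around: the HGAD-like group has stronger
#' alpha2 frontal phase coupling and weaker theta/alpha1 coupling than the
#' LGAD-like group, on a small planted frontal edge set.
#'
#' @param plantedEdges data.frame of from/to electrode pairs (default three
#'   frontal pairs).
#' @return named list (LGAD, HGAD) of coupling-spec lists, one per rhythm.
#' @export
defaultGroupSpecs <- function(plantedEdges = data.frame(
    from = c("FP1", "FP2", "F3"), to = c("F3", "F4", "F7"))) {
  mkEdges <- function(kappa, lag = pi / 3)
    cbind(plantedEdges, lag = lag, concentration = kappa)
  bands <- rhythmBands()
  list(
    LGAD = list(
      couplingSpec(bands$theta,  mkEdges(3)),
      couplingSpec(bands$alpha1, mkEdges(3)),
      couplingSpec(bands$alpha2, mkEdges(0.5)),
      couplingSpec(bands$beta)),
    HGAD = list(
      couplingSpec(bands$theta,  mkEdges(0.5)),
      couplingSpec(bands$alpha1, mkEdges(0.5)),
      couplingSpec(bands$alpha2, mkEdges(3)),
      couplingSpec(bands$beta)))
}

#' Generate one synthetic subject recording
#'
#' Each channel is a sum of per-rhythm narrowband oscillations plus white
#' noise. For every coupling edge (from, to) in a band's spec, the target
#' channel's oscillation in that band is phase-locked to the source
#' channel's with the stated lag and jitter concentration. Deterministic
#' given (masterSeed, group, subjectIndex).
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param group "LGAD" or "HGAD".
#' @param subjectIndex 1-based subject number within the group.
#' @return an \linkS4class{EEGRecording} with the group label set.
#' @export
generateSubject <- function(spec, group = c("LGAD", "HGAD"), subjectIndex) {
  group <- match.arg(group)
  n <- as.integer(round(spec$durationSeconds * spec$samplingRate))
  fs <- spec$samplingRate
  montage <- spec$montage
  nch <- length(montage)
  seed <- childSeed(spec$masterSeed,
                    (if (group == "HGAD") 500000L else 0L) + subjectIndex)
  data <- withSeed(seed, {
    acc <- matrix(0, nch, n)
    for (cs in spec$groupSpecs[[group]]) {
      center <- mean(cs$band)
      halfWidth <- diff(cs$band) / 2
      phases <- lapply(seq_len(nch), function(c)
        carrierPhase(n, fs, center, halfWidth, spec$driftSd))
      if (nrow(cs$edges)) {
        for (e in seq_len(nrow(cs$edges))) {
          src <- match(cs$edges$from[e], montage)
          tgt <- match(cs$edges$to[e], montage)
          jit <- blockJitter(n, fs, cs$edges$concentration[e])
          phases[[tgt]] <- phases[[src]] + cs$edges$lag[e] + jit
        }
      }
      for (c in seq_len(nch))
        acc[c, ] <- acc[c, ] + cs$oscillationAmplitude * cos(phases[[c]]) +
          rnorm(n, sd = cs$backgroundNoiseSd)
    }
    acc
  })
  EEGRecording(data, montage, fs,
               subjectId = sprintf("%s_%02d", group, subjectIndex),
               groupLabel = group)
}

#' Generate a full two-group cohort
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param outDir optional directory; when given, each recording is written
#'   in the delimited-matrix format plus a \code{manifest.csv}
#'   (subject_id, group, seed, file).
#' @return list with \code{recordings} (list of
#'   \linkS4class{EEGRecording}) and \code{manifest} (data.frame).
#' @export
generateCohort <- function(spec, outDir = NULL) {
  rows <- list(); recs <- list(); k <- 0L
  for (group in c("LGAD", "HGAD")) {
    for (s in seq_len(spec$nSubjectsPerGroup[[group]])) {
      k <- k + 1L
      rec <- generateSubject(spec, group, s)
      recs[[k]] <- rec
      seed <- childSeed(spec$masterSeed,
                        (if (group == "HGAD") 500000L else 0L) + s)
      file <- if (is.null(outDir)) NA_character_ else
        file.path(outDir, paste0(rec@subjectId, ".csv"))
      rows[[k]] <- data.frame(subject_id = rec@subjectId, group = group,
                              seed = seed, file = file)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(recs)) writeRecording(recs[[k]], manifest$file[k])
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
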