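#' Default pipeline configuration
#'
#' The defaults reproduce the standard analysis settings: 250 Hz input
#' downsampled to 125 Hz, zero-phase 4th-order Butterworth 4-30 Hz
#' broadband filter, 4 s epochs with 50\% overlap, the four canonical
#' rhythms, proportional thresholds 25-35\% in 1\% steps, 50
#' Maslov-Sneppen surrogates with 10 swaps per edge, epoch-level analysis
#' unit and alpha = 0.05.
#'
#' @param cohort optional \code{\link{cohortSpec}} to simulate the input
#'   cohort; alternatively set \code{inputDir} to a directory of
#'   delimited-matrix recordings with a \code{manifest.csv}.
#' @param inputDir optional input directory (ignored when \code{cohort} is
#'   given).
#' @param masterSeed integer master seed.
#' @return a config list; see \code{\link{validateConfig}} for the rules
#'   each field must satisfy.
#' @export
defaultConfig <- function(cohort = NULL, inputDir = NULL,
                          masterSeed = 20230413L) {
  list(cohort = cohort, inputDir = inputDir,
       montage = canonicalMontage(), inputRateHz = 250,
       targetRateHz = 125, broadband = c(4, 30), filterOrder = 4L,
       windowSeconds = 4, overlapFraction = 0.5, bands = rhythmBands(),
       fractions = seq(0.25, 0.35, by = 0.01), nSurrogates = 50L,
       swapsPerEdge = 10L, unit = "epoch", alpha = 0.05,
       edgeTrimFraction = 0.1, rhythmBeforeSegment = FALSE,
       phaseOnRecording = FALSE, computeNetworkMetrics = TRUE,
       masterSeed = as.integer(masterSeed))
}

#' Validate a pipeline configuration
#'
#' Checks every field against its rule and returns all violations; an
#' empty character vector means the config is valid. Validation never
#' throws.
#'
#' @param config a config list as from \code{\link{defaultConfig}}.
#' @return character vector of violation messages, possibly empty.
#' @export
validateConfig <- function(config) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  if (is.null(config$cohort) && is.null(config$inputDir))
    bad("input: either cohort or inputDir must be set")
  if (!length(config$montage) || anyDuplicated(config$montage))
    bad("montage: must be a non-empty list of unique labels")
  for (fld in c("inputRateHz", "targetRateHz", "windowSeconds", "alpha"))
    if (!is.numeric(config[[fld]]) || length(config[[fld]]) != 1L ||
        config[[fld]] <= 0)
      bad(paste0(fld, ": must be a single positive number"))
  if (is.numeric(config$inputRateHz) && is.numeric(config$targetRateHz)) {
    f <- config$inputRateHz / config$targetRateHz
    if (abs(f - round(f)) > 1e-9)
      bad("targetRateHz: must divide inputRateHz by an integer factor")
  }
  if (!is.numeric(config$overlapFraction) ||
      config$overlapFraction < 0 || config$overlapFraction >= 1)
    bad("overlapFraction: must lie in [0, 1)")
  if (length(config$broadband) != 2L || config$broadband[1] <= 0 ||
      config$broadband[1] >= config$broadband[2])
    bad("broadband: must be c(low, high) with 0 < low < high")
  else if (is.numeric(config$targetRateHz) &&
           config$broadband[2] >= config$targetRateHz / 2)
    bad("broadband: high edge at or above target Nyquist")
  if (!length(config$bands))
    bad("bands: must list at least one rhythm band")
  else for (b in seq_along(config$bands)) {
    bb <- config$bands[[b]]
    if (!is.numeric(bb) || length(bb) != 2L || bb[1] <= 0 || bb[1] >= bb[2])
      bad(paste0("bands[", names(config$bands)[b],
                 "]: must be c(low, high) with 0 < low < high"))
  }
  if (!length(config$fractions) ||
      any(config$fractions <= 0 | config$fractions > 1))
    bad("fractions: each density fraction must lie in (0, 1]")
  if (!is.numeric(config$nSurrogates) || config$nSurrogates < 1)
    bad("nSurrogates: must be >= 1")
  if (!is.numeric(config$swapsPerEdge) || config$swapsPerEdge < 1)
    bad("swapsPerEdge: must be >= 1")
  if (!config$unit %in% c("epoch", "subject"))
    bad("unit: must be 'epoch' or 'subject'")
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    bad("alpha: must lie in (0, 1)")
  if (!is.numeric(config$edgeTrimFraction) || config$edgeTrimFraction < 0 ||
      config$edgeTrimFraction >= 0.5)
    bad("edgeTrimFraction: must lie in [0, 0.5)")
  v
}

#' Read / write a pipeline config as YAML
#'
#' \code{cohort} round-trips through its plain-list representation;
#' coupling-edge data.frames are stored as column lists.
#'
#' @param path YAML file path.
#' @param config a config list.
#' @name configIO
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$bands))
    cfg$bands <- lapply(cfg$bands, as.numeric)
  if (!is.null(cfg$cohort)) {
    co <- cfg$cohort
    co$nSubjectsPerGroup <- unlist(co$nSubjectsPerGroup)
    co$groupSpecs <- lapply(co$groupSpecs, function(gs) lapply(gs, function(cs) {
      couplingSpec(as.numeric(cs$band),
                   if (length(cs$edges$from)) as.data.frame(cs$edges) else NULL,
                   cs$backgroundNoiseSd, cs$oscillationAmplitude)
    }))
    cfg$cohort <- do.call(cohortSpec, co[c("nSubjectsPerGroup",
      "durationSeconds", "samplingRate", "montage", "groupSpecs",
      "masterSeed", "driftSd")])
  }
  cfg
}

#' @rdname configIO
#' @export
writeConfig <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$cohort)) {
    co <- cfg$cohort
    co$nSubjectsPerGroup <- as.list(co$nSubjectsPerGroup)
    co$groupSpecs <- lapply(co$groupSpecs, function(gs) lapply(gs, function(cs) {
      cs$edges <- as.list(cs$edges)
      cs
    }))
    cfg$cohort <- co
  }
  # precision 17 round-trips IEEE doubles exactly (seeded determinism
  # depends on bit-identical lags and band edges)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

# preprocess one recording into per-band epoch sets per the config
preprocessRecording <- function(rec, config) {
  rec <- removeArtifacts(rec)
  if (rec@samplingRate != config$targetRateHz)
    rec <- downsample(rec, config$targetRateHz)
  rec <- bandpassFilter(rec, config$broadband[1], config$broadband[2],
                        config$filterOrder)
  if (isTRUE(config$rhythmBeforeSegment)) {
    bandsets <- lapply(seq_along(config$bands), function(b) {
      band <- config$bands[[b]]
      fr <- bandpassFilter(rec, band[1], band[2], config$filterOrder)
      es <- segmentEpochs(fr, config$windowSeconds, config$overlapFraction)
      es@band <- names(config$bands)[b]
      es
    })
    names(bandsets) <- names(config$bands)
    bandsets
  } else {
    epochs <- segmentEpochs(rec, config$windowSeconds, config$overlapFraction)
    extractRhythms(epochs, config$bands, config$filterOrder)
  }
}

# per-band PLI matrices for one recording; honours the phaseOnRecording
# switch (phase computed once on the band-filtered continuous recording,
# then cut into epochs) vs the default per-epoch phase estimation.
connectivityForRecording <- function(rec, config) {
  if (!isTRUE(config$phaseOnRecording)) {
    bandsets <- preprocessRecording(rec, config)
    return(lapply(bandsets, epochConnectivity,
                  edgeTrimFraction = config$edgeTrimFraction))
  }
  rec2 <- removeArtifacts(rec)
  if (rec2@samplingRate != config$targetRateHz)
    rec2 <- downsample(rec2, config$targetRateHz)
  rec2 <- bandpassFilter(rec2, config$broadband[1], config$broadband[2],
                         config$filterOrder)
  fs <- rec2@samplingRate
  win <- as.integer(round(config$windowSeconds * fs))
  step <- as.integer(round(win * (1 - config$overlapFraction)))
  nEp <- (ncol(rec2@data) - win) %/% step + 1L
  out <- lapply(seq_along(config$bands), function(b) {
    band <- config$bands[[b]]
    fr <- bandpassFilter(rec2, band[1], band[2], config$filterOrder)
    phases <- t(apply(fr@data, 1L, instantaneousPhase))
    lapply(seq_len(nEp), function(e) {
      s <- (e - 1L) * step + 1L
      ph <- phases[, s:(s + win - 1L), drop = FALSE]
      nch <- nrow(ph)
      v <- matrix(0, nch, nch)
      for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
        dphi <- trimEnds(phaseDifference(ph[i, ], ph[j, ]),
                         config$edgeTrimFraction)
        v[i, j] <- v[j, i] <- pli(dphi)
      }
      ConnectivityMatrix(v, rec2@channelNames, names(config$bands)[b],
                         as.character(e))
    })
  })
  names(out) <- names(config$bands)
  out
}

loadInputRecordings <- function(config) {
  if (!is.null(config$cohort)) return(generateCohort(config$cohort)$recordings)
  manifestPath <- file.path(config$inputDir, "manifest.csv")
  if (!file.exists(manifestPath))
    stop("read stage: no manifest.csv in ", config$inputDir)
  man <- utils::read.csv(manifestPath)
  if (!nrow(man)) stop("read stage: empty manifest in ", config$inputDir)
  lapply(seq_len(nrow(man)), function(k)
    readRecording(file.path(config$inputDir, basename(man$file[k])),
                  "delimited_matrix", samplingRate = config$inputRateHz,
                  montage = config$montage, subjectId = man$subject_id[k],
                  groupLabel = man$group[k]))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate/load, preprocessing, per-rhythm PLI connectivity,
#' thresholded network metrics, and two-group statistics, writing all
#' result tables and a machine-readable run log to \code{outputDir}.
#' Re-running with an identical config and master seed reproduces every
#' output exactly.
#'
#' Outputs per band directory: \code{edge_table.tsv} (one ANOVA row per
#' electrode pair), \code{metrics.tsv} (per analysis-unit sweep-mean Cw,
#' Lw, sigma), \code{metric_comparison.tsv}, \code{frontal_summary.tsv},
#' and the subject- or epoch-level mean PLI matrix; plus a top-level
#' \code{run_log.json}.
#'
#' @param config a valid config list (see \code{\link{defaultConfig}}).
#' @param outputDir output directory, created if needed.
#' @return invisibly, a list with per-band results (edge comparisons,
#'   metric tables, comparisons, frontal summaries) and the run log.
#' @export
runPipeline <- function(config, outputDir) {
  violations <- validateConfig(config)
  if (length(violations))
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  recs <- loadInputRecordings(config)
  groups <- vapply(recs, function(r) r@groupLabel, "")
  if (!all(c("LGAD", "HGAD") %in% groups))
    stop("read stage: inputs must contain both LGAD and HGAD recordings")

  bandNames <- names(config$bands)
  perBand <- lapply(bandNames, function(b) list())
  names(perBand) <- bandNames
  log <- list(config_echo = config[setdiff(names(config), "cohort")],
              master_seed = config$masterSeed,
              n_recordings = length(recs), stages = list())

  # connectivity stage: per subject per band
  connBySubject <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    connBySubject[[k]] <- connectivityForRecording(recs[[k]], config)
    nEp <- length(connBySubject[[k]][[1L]])
    log$stages[[length(log$stages) + 1L]] <- list(
      stage = "connectivity", subject = recs[[k]]@subjectId,
      group = groups[k], epochs = nEp,
      pli_values_per_epoch_per_band = length(config$montage) *
        (length(config$montage) - 1) / 2,
      bands = length(bandNames))
  }

  nPairs <- length(config$montage) * (length(config$montage) - 1) / 2
  results <- list()
  for (b in bandNames) {
    # analysis units per group
    unitsByGroup <- list(HGAD = list(), LGAD = list())
    for (k in seq_along(recs)) {
      mats <- connBySubject[[k]][[b]]
      g <- groups[k]
      if (config$unit == "subject") {
        unitsByGroup[[g]] <- c(unitsByGroup[[g]], list(meanConnectivity(mats)))
      } else {
        unitsByGroup[[g]] <- c(unitsByGroup[[g]], mats)
      }
    }
    comp <- edgewiseComparison(unitsByGroup$HGAD, unitsByGroup$LGAD,
                               alpha = config$alpha, unit = config$unit)
    fsum <- frontalSummary(comp,
                           intersect(frontalElectrodes(), config$montage))

    bandDir <- file.path(outputDir, b)
    dir.create(bandDir, showWarnings = FALSE)
    utils::write.table(edgeResults(comp), file.path(bandDir, "edge_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (g in c("HGAD", "LGAD"))
      writeConnectivity(meanConnectivity(unitsByGroup[[g]]),
                        file.path(bandDir, paste0("mean_pli_", g, ".tsv")))

    metricTab <- NULL; mcomp <- NULL
    if (isTRUE(config$computeNetworkMetrics)) {
      rows <- list()
      for (g in c("HGAD", "LGAD")) {
        mats <- unitsByGroup[[g]]
        for (u in seq_along(mats)) {
          sw <- metricsOverSweep(mats[[u]], config$fractions,
                                 config$nSurrogates, config$swapsPerEdge,
                                 seed = childSeed(config$masterSeed,
                                   match(b, bandNames) * 100000L +
                                   (g == "HGAD") * 50000L + u))
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(group = g, unit_index = u, band = b), sw$summary)
        }
      }
      metricTab <- do.call(rbind, rows)
      mcomp <- metricwiseComparison(
        metricTab[metricTab$group == "HGAD", ],
        metricTab[metricTab$group == "LGAD", ],
        alpha = config$alpha, band = b, unit = config$unit)
      utils::write.table(metricTab, file.path(bandDir, "metrics.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(metricResults(mcomp),
                         file.path(bandDir, "metric_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    fsumTab <- data.frame(band = b,
                          n_sig = fsum$n_significant_edges,
                          n_frontal = fsum$n_frontal_related,
                          fraction = fsum$frontal_fraction,
                          n_HGAD_higher = fsum$n_increased_in_HGAD)
    utils::write.table(fsumTab, file.path(bandDir, "frontal_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log$stages[[length(log$stages) + 1L]] <- list(
      stage = "group_stats", band = b,
      units_HGAD = length(unitsByGroup$HGAD),
      units_LGAD = length(unitsByGroup$LGAD),
      edges_tested = nrow(edgeResults(comp)),
      frontal_ratio = sprintf("%d/%d", fsum$n_frontal_related,
                              fsum$n_significant_edges))
    stopifnot(nrow(edgeResults(comp)) == nPairs)
    results[[b]] <- list(edgewise = comp, frontal = fsum,
                         metrics = metricTab, metricComparison = mcomp)
  }
  log$pli_values_per_band <- nPairs
  log$pli_values_total <- nPairs * length(bandNames)
  jsonlite::write_json(log, file.path(outputDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(list(results = results, log = log, outputDir = outputDir))
}
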