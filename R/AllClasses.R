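#' EEGRecording: a multichannel EEG recording
#'
#' Channels-by-samples matrix of microvolt signals with electrode labels, a
#' sampling rate, a subject identifier and an optional group label.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot channelNames character vector, one label per row of \code{data}.
#' @slot samplingRate sampling rate in Hz (positive).
#' @slot subjectId opaque subject identifier.
#' @slot groupLabel "LGAD", "HGAD" or NA when no grouping applies.
#'
#' @export
setClass("EEGRecording",
  representation(data = "matrix", channelNames = "character",
                 samplingRate = "numeric", subjectId = "character",
                 groupLabel = "character"),
  prototype(subjectId = "anonymous", groupLabel = NA_character_))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, sprintf("data has %d rows but %d channel names",
                          nrow(object@data), length(object@channelNames)))
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "duplicated channel names")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@data) && !all(is.finite(object@data)))
    msg <- c(msg, "data contains NaN/Inf samples")
  if (!is.na(object@groupLabel) && !object@groupLabel %in% c("LGAD", "HGAD"))
    msg <- c(msg, "groupLabel must be 'LGAD', 'HGAD' or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param channelNames electrode labels in row order.
#' @param samplingRate Hz.
#' @param subjectId subject identifier string.
#' @param groupLabel optional "LGAD"/"HGAD".
#' @return an \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(data, channelNames, samplingRate,
                         subjectId = "anonymous", groupLabel = NA_character_) {
  data <- as.matrix(data)
  rownames(data) <- channelNames
  new("EEGRecording", data = data, channelNames = as.character(channelNames),
      samplingRate = as.numeric(samplingRate),
      subjectId = as.character(subjectId),
      groupLabel = as.character(groupLabel))
}

#' EpochSet: fixed-length overlapping windows from one recording
#'
#' @slot epochs list of channels x window-samples matrices, all same shape.
#' @slot windowSeconds window length in seconds.
#' @slot overlapFraction fractional overlap in [0, 1).
#' @slot band name of the rhythm band the epochs are filtered to, or
#'   "broadband".
#' @slot channelNames electrode labels.
#' @slot samplingRate Hz.
#' @slot subjectId source subject.
#' @slot groupLabel source group label.
#' @export
setClass("EpochSet",
  representation(epochs = "list", windowSeconds = "numeric",
                 overlapFraction = "numeric", band = "character",
                 channelNames = "character", samplingRate = "numeric",
                 subjectId = "character", groupLabel = "character"),
  prototype(band = "broadband", groupLabel = NA_character_))

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (length(object@epochs)) {
    dims <- vapply(object@epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all epochs must share an identical shape")
    if (dims[1, 1] != length(object@channelNames))
      msg <- c(msg, "epoch row count differs from channelNames length")
  }
  if (object@overlapFraction < 0 || object@overlapFraction >= 1)
    msg <- c(msg, "overlapFraction must lie in [0, 1)")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: symmetric PLI matrix for one epoch and rhythm
#'
#' @slot values symmetric N x N matrix with zero diagonal, entries in [0, 1].
#' @slot channelNames electrode labels (row/column order).
#' @slot band rhythm-band name or "broadband".
#' @slot epochIndex epoch number, or "mean" for an epoch average.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", channelNames = "character",
                 band = "character", epochIndex = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@channelNames))
    msg <- c(msg, "dimension differs from channelNames length")
  if (length(v)) {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "values must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values symmetric numeric matrix with zero diagonal, entries in
#'   [0, 1].
#' @param channelNames electrode labels.
#' @param band rhythm-band name.
#' @param epochIndex epoch identifier or "mean".
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
ConnectivityMatrix <- function(values, channelNames, band = "broadband",
                               epochIndex = "mean") {
  dimnames(values) <- list(channelNames, channelNames)
  new("ConnectivityMatrix", values = values,
      channelNames = as.character(channelNames), band = as.character(band),
      epochIndex = as.character(epochIndex))
}

#' WeightedNetwork: proportionally thresholded sparse weighted graph
#'
#' @slot nodes ordered electrode labels.
#' @slot edges data.frame with integer columns i < j (1-based node indices)
#'   and numeric weight in (0, 1].
#' @slot densityFraction the proportional threshold that produced the graph.
#' @export
setClass("WeightedNetwork",
  representation(nodes = "character", edges = "data.frame",
                 densityFraction = "numeric"))

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  msg <- character(0)
  if (!all(c("i", "j", "weight") %in% names(e)))
    msg <- c(msg, "edges needs columns i, j, weight")
  else if (nrow(e)) {
    if (any(e$i >= e$j)) msg <- c(msg, "edges must satisfy i < j (no self-loops)")
    if (anyDuplicated(e[, c("i", "j")])) msg <- c(msg, "duplicate edges")
    if (any(e$weight <= 0)) msg <- c(msg, "all weights must be positive")
    if (max(e$j) > length(object@nodes)) msg <- c(msg, "edge index beyond node list")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedNetwork
#'
#' @param nodes ordered node labels.
#' @param edges data.frame with columns i, j (1-based indices, i < j) and
#'   weight (positive).
#' @param densityFraction the proportional threshold that produced the
#'   graph, if any.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
WeightedNetwork <- function(nodes, edges, densityFraction = NA_real_) {
  edges <- as.data.frame(edges)
  new("WeightedNetwork", nodes = as.character(nodes), edges = edges,
      densityFraction = as.numeric(densityFraction))
}

#' GroupComparison: edgewise and metric-wise two-group ANOVA results
#'
#' @slot band rhythm-band name.
#' @slot unit analysis unit, "epoch" or "subject".
#' @slot edgeResults data.frame (i, j, node_i, node_j, F, p, direction,
#'   significant), one row per upper-triangle edge, ordered by (i, j).
#' @slot metricResults data.frame (metric, F, p, mean_HGAD, mean_LGAD,
#'   significant), possibly empty.
#' @slot alpha significance level.
#' @export
setClass("GroupComparison",
  representation(band = "character", unit = "character",
                 edgeResults = "data.frame", metricResults = "data.frame",
                 alpha = "numeric"),
  prototype(unit = "epoch", alpha = 0.05,
            edgeResults = data.frame(), metricResults = data.frame()))

## ---- accessors ----------------------------------------------------------

#' Electrode labels accessor
#' @param object an EEGRecording, EpochSet or ConnectivityMatrix.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
#' @export
setMethod("channelNames", "ConnectivityMatrix", function(object) object@channelNames)

#' Sampling rate accessor
#' @param object an EEGRecording or EpochSet.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)

#' Number of epochs in an EpochSet
#' @param object an EpochSet.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @export
setMethod("nEpochs", "EpochSet", function(object) length(object@epochs))

#' Extract one epoch matrix
#' @param object an EpochSet.
#' @param i epoch index.
#' @export
setGeneric("getEpoch", function(object, i) standardGeneric("getEpoch"))
#' @export
setMethod("getEpoch", "EpochSet", function(object, i) object@epochs[[i]])

#' Connectivity values as a plain matrix
#' @param object a ConnectivityMatrix.
#' @export
setGeneric("connectivityValues", function(object) standardGeneric("connectivityValues"))
#' @export
setMethod("connectivityValues", "ConnectivityMatrix", function(object) object@values)

#' Edge table of a WeightedNetwork
#' @param object a WeightedNetwork.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @export
setMethod("networkEdges", "WeightedNetwork", function(object) object@edges)

#' Node labels of a WeightedNetwork
#' @param object a WeightedNetwork.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @export
setMethod("networkNodes", "WeightedNetwork", function(object) object@nodes)

#' Edgewise result table of a GroupComparison
#' @param object a GroupComparison.
#' @export
setGeneric("edgeResults", function(object) standardGeneric("edgeResults"))
#' @export
setMethod("edgeResults", "GroupComparison", function(object) object@edgeResults)

#' Metric-wise result table of a GroupComparison
#' @param object a GroupComparison.
#' @export
setGeneric("metricResults", function(object) standardGeneric("metricResults"))
#' @export
setMethod("metricResults", "GroupComparison", function(object) object@metricResults)

## ---- show methods -------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s'%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId,
              if (is.na(object@groupLabel)) "" else paste0(" [", object@groupLabel, "]"),
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat("  channels:", paste(object@channelNames, collapse = " "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  ns <- if (length(object@epochs)) ncol(object@epochs[[1]]) else 0L
  cat(sprintf("EpochSet [%s] '%s': %d epochs of %d channels x %d samples (%g s, overlap %g) @ %g Hz\n",
              object@band, object@subjectId, length(object@epochs),
              length(object@channelNames), ns, object@windowSeconds,
              object@overlapFraction, object@samplingRate))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- length(object@channelNames)
  cat(sprintf("ConnectivityMatrix [%s, epoch %s]: %d nodes, %d pair values, mean PLI %.3f\n",
              object@band, object@epochIndex, n, n * (n - 1) / 2,
              mean(object@values[upper.tri(object@values)])))
})

setMethod("show", "WeightedNetwork", function(object) {
  cat(sprintf("WeightedNetwork: %d nodes, %d edges (density fraction %s)\n",
              length(object@nodes), nrow(object@edges),
              format(object@densityFraction)))
})

setMethod("show", "GroupComparison", function(object) {
  er <- object@edgeResults
  cat(sprintf("GroupComparison [%s, unit=%s, alpha=%g]: %d edges tested, %d significant",
              object@band, object@unit, object@alpha, nrow(er),
              if (nrow(er)) sum(er$significant) else 0L))
  if (nrow(object@metricResults))
    cat(sprintf("; %d metrics tested", nrow(object@metricResults)))
  cat("\n")
})
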