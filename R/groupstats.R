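#' One-way fixed-effects ANOVA for two groups
#'
#' Classical homoscedastic one-way ANOVA (via \code{stats::oneway.test}
#' with \code{var.equal = TRUE}); for two groups F equals the square of the
#' pooled-variance t statistic, with df (1, nA + nB - 2).
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with \code{F}, \code{p} and \code{df} (length-2). When both
#'   within-group variances are zero and the means are equal, F is NA and p
#'   is 1 with \code{degenerate = TRUE}; zero within-variance with unequal
#'   means gives F = Inf, p = 0.
#' @export
onewayAnova <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L)
    stop("each group needs at least 2 observations")
  y <- c(groupA, groupB)
  g <- factor(rep(c("A", "B"), c(nA, nB)))
  ssw <- sum((groupA - mean(groupA))^2) + sum((groupB - mean(groupB))^2)
  if (ssw == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(F = NA_real_, p = 1, df = c(1, nA + nB - 2L),
                  degenerate = TRUE))
    return(list(F = Inf, p = 0, df = c(1, nA + nB - 2L), degenerate = FALSE))
  }
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), degenerate = FALSE)
}

# stack upper-triangle PLI values: rows = matrices, cols = edges
stackUpperTri <- function(mats, ch) {
  n <- length(ch)
  ut <- upper.tri(matrix(0, n, n))
  t(vapply(mats, function(m) {
    if (!identical(m@channelNames, ch)) stop("montage mismatch across matrices")
    connectivityValues(m)[ut]
  }, numeric(n * (n - 1) / 2)))
}

#' Edgewise two-group comparison of PLI matrices
#'
#' One one-way ANOVA per upper-triangle edge (120 tests for the canonical
#' 16-electrode montage) between two groups of connectivity matrices.
#' Direction is taken from the group sample means. Uncorrected p-values are
#' compared with \code{alpha} by default, mirroring common practice in the
#' field; set \code{adjust = "BH"} for Benjamini-Hochberg control instead.
#'
#' @param matricesHGAD,matricesLGAD lists of
#'   \linkS4class{ConnectivityMatrix} (>= 2 per group), same montage and
#'   band.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @param unit analysis-unit label recorded in the result ("epoch" or
#'   "subject").
#' @return a \linkS4class{GroupComparison} whose \code{edgeResults} rows are
#'   ordered by (i, j) with columns i, j, node_i, node_j, F, p, direction
#'   ("HGAD_higher"/"LGAD_higher"), significant.
#' @export
edgewiseComparison <- function(matricesHGAD, matricesLGAD, alpha = 0.05,
                               adjust = c("none", "BH"), unit = "epoch") {
  adjust <- match.arg(adjust)
  if (length(matricesHGAD) < 2L || length(matricesLGAD) < 2L)
    stop("each group needs at least 2 matrices")
  ch <- matricesHGAD[[1L]]@channelNames
  band <- matricesHGAD[[1L]]@band
  a <- stackUpperTri(matricesHGAD, ch)
  b <- stackUpperTri(matricesLGAD, ch)
  n <- length(ch)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    node_i = ch[idx[, 1L]], node_j = ch[idx[, 2L]],
                    F = NA_real_, p = NA_real_,
                    direction = NA_character_, significant = NA)
  for (e in seq_len(nrow(idx))) {
    an <- onewayAnova(a[, e], b[, e])
    res$F[e] <- an$F
    res$p[e] <- an$p
    res$direction[e] <- if (mean(a[, e]) >= mean(b[, e])) "HGAD_higher" else "LGAD_higher"
  }
  padj <- if (adjust == "BH") stats::p.adjust(res$p, method = "BH") else res$p
  res$significant <- padj < alpha
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  new("GroupComparison", band = band, unit = unit, edgeResults = res,
      metricResults = data.frame(), alpha = alpha)
}

#' Frontal-involvement summary of significant edges
#'
#' An edge is frontal-related iff at least one endpoint is a frontal
#' electrode. Also counts significant edges whose PLI is higher in the
#' HGAD-like group.
#'
#' @param comp a \linkS4class{GroupComparison} with edge results.
#' @param frontal frontal electrode labels (default
#'   \code{frontalElectrodes()}).
#' @return list: n_significant_edges, n_frontal_related, frontal_fraction
#'   (NA when no edge is significant), n_increased_in_HGAD,
#'   frontal_electrodes.
#' @export
frontalSummary <- function(comp, frontal = frontalElectrodes()) {
  stopifnot(is(comp, "GroupComparison"))
  er <- comp@edgeResults
  montage <- unique(c(er$node_i, er$node_j))
  missing <- setdiff(frontal, montage)
  if (length(missing))
    stop("frontal electrode not in montage: ", paste(missing, collapse = ", "))
  sig <- er[er$significant %in% TRUE, , drop = FALSE]
  isFrontal <- sig$node_i %in% frontal | sig$node_j %in% frontal
  nSig <- nrow(sig)
  list(n_significant_edges = nSig,
       n_frontal_related = sum(isFrontal),
       frontal_fraction = if (nSig > 0) sum(isFrontal) / nSig else NA_real_,
       n_increased_in_HGAD = sum(sig$direction == "HGAD_higher"),
       frontal_electrodes = frontal)
}

#' Metric-wise two-group comparison
#'
#' One one-way ANOVA per network metric (Cw, Lw, sigma) on sweep-mean
#' values between two groups.
#'
#' @param metricsHGAD,metricsLGAD data.frames of per-record metrics with
#'   columns Cw, Lw, sigma (one row per epoch or subject), >= 2 rows per
#'   group.
#' @param alpha significance level (default 0.05).
#' @param band band label recorded in the result.
#' @param unit analysis-unit label.
#' @return a \linkS4class{GroupComparison} with \code{metricResults}
#'   columns metric, F, p, mean_HGAD, mean_LGAD, significant.
#' @export
metricwiseComparison <- function(metricsHGAD, metricsLGAD, alpha = 0.05,
                                 band = "broadband", unit = "epoch") {
  if (NROW(metricsHGAD) < 2L || NROW(metricsLGAD) < 2L)
    stop("each group needs at least 2 metric records")
  metrics <- c("Cw", "Lw", "sigma")
  rows <- lapply(metrics, function(mn) {
    a <- metricsHGAD[[mn]]; b <- metricsLGAD[[mn]]
    an <- onewayAnova(a, b)
    data.frame(metric = mn, F = an$F, p = an$p,
               mean_HGAD = mean(a), mean_LGAD = mean(b),
               significant = an$p < alpha)
  })
  new("GroupComparison", band = band, unit = unit,
      edgeResults = data.frame(), metricResults = do.call(rbind, rows),
      alpha = alpha)
}
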