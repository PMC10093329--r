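#' Proportional threshold of a connectivity matrix
#'
#' Sorts the \eqn{N(N-1)/2} upper-triangle weights in descending order and
#' retains the top \code{round(fraction * N(N-1)/2)} of them (round half
#' up) as edges carrying their PLI values. Ties at the cut are broken by
#' lexicographic (i, j) order for determinism. Isolated nodes are reported
#' via an attribute, never repaired: the proportional-threshold range is
#' meant to be chosen so none arise.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param fraction density fraction in (0, 1].
#' @return a \linkS4class{WeightedNetwork}; attribute \code{"isolated"}
#'   holds the labels of any isolated nodes.
#' @export
proportionalThreshold <- function(m, fraction) {
  stopifnot(is(m, "ConnectivityMatrix"))
  if (!(fraction > 0 && fraction <= 1))
    stop("density fraction must lie in (0, 1]")
  v <- m@values
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[ut]
  k <- roundHalfUp(fraction * nrow(ut))
  ord <- order(-w, ut[, 1L], ut[, 2L])
  take <- ord[seq_len(k)]
  keepPos <- w[take] > 0
  if (!all(keepPos)) {
    warning(sprintf("%d retained edges had zero weight and were dropped",
                    sum(!keepPos)))
    take <- take[keepPos]
  }
  edges <- data.frame(i = ut[take, 1L], j = ut[take, 2L], weight = w[take])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  net <- WeightedNetwork(m@channelNames, edges, fraction)
  deg <- tabulate(c(edges$i, edges$j), nbins = n)
  attr(net, "isolated") <- m@channelNames[deg == 0L]
  net
}

#' Threshold sweep over density fractions
#'
#' One proportionally thresholded network per fraction; the default sweep
#' 25\% to 35\% in 1\% steps yields 11 networks.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param fractions numeric vector of density fractions in (0, 1].
#' @return list of \linkS4class{WeightedNetwork}, one per fraction.
#' @export
thresholdSweep <- function(m, fractions = seq(0.25, 0.35, by = 0.01)) {
  if (!length(fractions)) stop("empty fraction list")
  lapply(fractions, function(f) proportionalThreshold(m, f))
}

# adjacency + weight matrices from a WeightedNetwork
netMatrices <- function(net) {
  n <- length(net@nodes)
  W <- matrix(0, n, n)
  e <- net@edges
  if (nrow(e)) {
    idx <- cbind(e$i, e$j)
    W[idx] <- e$weight
    W[idx[, 2:1, drop = FALSE]] <- e$weight
  }
  W
}

#' Weighted clustering coefficient
#'
#' Per node i with binary degree \eqn{k_i} and strength
#' \eqn{S_i = \sum_j w_{ij}}:
#' \deqn{C_i^w = \frac{1}{S_i (k_i - 1)} \sum_{j \ne h}
#'   \frac{w_{ij} + w_{ih}}{2} a_{ij} a_{ih} a_{jh}}
#' with the sum over ordered neighbour pairs (j, h) whose closing edge j-h
#' exists, so that \eqn{C_i^w \in [0, 1]} and equal weights reduce to the
#' binary clustering coefficient. Nodes of degree < 2 (for which the
#' normalisation is undefined) receive 0 and are included in the network
#' mean \eqn{C^w = \frac{1}{N}\sum_i C_i^w}.
#'
#' @param net a non-empty \linkS4class{WeightedNetwork}.
#' @return list with \code{perNode} (named numeric, one per node) and
#'   \code{mean}.
#' @export
weightedClustering <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  if (!nrow(net@edges)) stop("empty network")
  W <- netMatrices(net)
  A <- (W > 0) * 1
  k <- rowSums(A)
  S <- rowSums(W)
  # ordered-pair sum collapses to sum_j W_ij (A^2)_ij by the j<->h symmetry
  num <- rowSums(W * (A %*% A))
  perNode <- ifelse(k >= 2, num / (S * pmax(k - 1, 1)), 0)
  names(perNode) <- net@nodes
  list(perNode = perNode, mean = mean(perNode))
}

#' Weighted characteristic path length
#'
#' Shortest paths on edge lengths \eqn{1/w_{ij}} (Dijkstra via igraph);
#' \eqn{L^w} is the mean over ordered node pairs. If any pair is
#' unreachable the mean is taken over reachable pairs only and the result
#' is flagged, keeping the anomaly visible while leaving downstream ratios
#' computable.
#'
#' @param net a non-empty \linkS4class{WeightedNetwork}.
#' @return list with \code{value} (mean shortest path length),
#'   \code{disconnected} (logical) and \code{unreachablePairs} (count of
#'   unordered unreachable pairs).
#' @export
weightedPathLength <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  e <- net@edges
  if (!nrow(e)) stop("empty network")
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j), directed = FALSE,
    vertices = data.frame(name = seq_along(net@nodes)))
  d <- igraph::distances(g, weights = 1 / e$weight, algorithm = "dijkstra")
  off <- d[upper.tri(d)]
  unreach <- sum(!is.finite(off))
  list(value = mean(off[is.finite(off)]),
       disconnected = unreach > 0L,
       unreachablePairs = unreach)
}

#' Maslov-Sneppen degree-preserving rewiring
#'
#' Randomises topology by repeated double-edge swaps
#' (a-b, c-d) -> (a-d, c-b), rejecting swaps that would create self-loops
#' or duplicate edges. Each edge's weight travels with it, so node count,
#' edge count, every node's degree and the weight multiset are all
#' preserved. Deterministic for a fixed seed.
#'
#' @param net a \linkS4class{WeightedNetwork} with >= 2 edges.
#' @param swapsPerEdge target number of successful swaps per edge
#'   (default 10).
#' @param seed integer seed.
#' @param attemptFactor attempt budget as a multiple of the target swap
#'   count (default 100).
#' @return a rewired \linkS4class{WeightedNetwork}; if no valid swap was
#'   found within the budget the input topology is returned with attribute
#'   \code{"rewireExhausted"} = TRUE.
#' @export
maslovSneppenRewire <- function(net, swapsPerEdge = 10L, seed,
                                attemptFactor = 100L) {
  stopifnot(is(net, "WeightedNetwork"), swapsPerEdge >= 1L)
  e <- net@edges
  m <- nrow(e)
  if (m < 2L) stop("need at least 2 edges to rewire")
  n <- length(net@nodes)
  ei <- e$i; ej <- e$j; ew <- e$weight
  target <- swapsPerEdge * m
  budget <- attemptFactor * target
  withSeed(seed, {
    present <- new.env(hash = TRUE, size = 2L * m)
    key <- function(a, b) paste0(min(a, b), "_", max(a, b))
    for (t in seq_len(m)) assign(key(ei[t], ej[t]), TRUE, envir = present)
    done <- 0L; attempts <- 0L
    while (done < target && attempts < budget) {
      attempts <- attempts + 1L
      p <- sample.int(m, 2L)
      a <- ei[p[1L]]; b <- ej[p[1L]]; c <- ei[p[2L]]; d <- ej[p[2L]]
      # randomly choose which endpoints to exchange
      if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed: a-d and c-b
      if (a == d || c == b) next
      if (length(intersect(c(a, b), c(c, d)))) next
      k1 <- key(a, d); k2 <- key(c, b)
      if (exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE)) next
      rm(list = c(key(a, b), key(c, d)), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      ei[p[1L]] <- min(a, d); ej[p[1L]] <- max(a, d)
      ei[p[2L]] <- min(c, b); ej[p[2L]] <- max(c, b)
      done <- done + 1L
    }
  })
  out <- data.frame(i = ei, j = ej, weight = ew)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  res <- WeightedNetwork(net@nodes, out, net@densityFraction)
  if (done == 0L) {
    warning("no valid degree-preserving swap found; topology unchanged")
    attr(res, "rewireExhausted") <- TRUE
  }
  res
}

#' Small-world index against Maslov-Sneppen surrogates
#'
#' \eqn{\sigma = (C^w / C^w_{rand}) / (L^w / L^w_{rand})}, where the random
#' baselines are means over \code{nSurrogates} independent degree-preserving
#' surrogates (child seeds derived from \code{seed} by
#' \code{\link{childSeed}}). \eqn{\sigma > 1} indicates clustering above the
#' random baseline at near-random path length.
#'
#' @param net a non-empty \linkS4class{WeightedNetwork}.
#' @param nSurrogates number of surrogate networks (default 50).
#' @param swapsPerEdge swaps per edge per surrogate (default 10).
#' @param seed integer seed.
#' @return a one-row data.frame with columns threshold, Cw, Lw, sigma,
#'   c_rand, l_rand, n_surrogates, disconnected (TRUE if the network or any
#'   surrogate had unreachable pairs). sigma is NA when no surrogate
#'   contains a triangle.
#' @export
smallWorldSigma <- function(net, nSurrogates = 50L, swapsPerEdge = 10L, seed) {
  stopifnot(nSurrogates >= 1L)
  cw <- weightedClustering(net)$mean
  lw <- weightedPathLength(net)
  cr <- numeric(nSurrogates)
  lr <- numeric(nSurrogates)
  disc <- lw$disconnected
  for (s in seq_len(nSurrogates)) {
    sur <- maslovSneppenRewire(net, swapsPerEdge, childSeed(seed, s))
    cr[s] <- weightedClustering(sur)$mean
    pl <- weightedPathLength(sur)
    lr[s] <- pl$value
    disc <- disc || pl$disconnected
  }
  cRand <- mean(cr)
  lRand <- mean(lr)
  sigma <- if (cRand > 0) (cw / cRand) / (lw$value / lRand) else NA_real_
  data.frame(threshold = net@densityFraction, Cw = cw, Lw = lw$value,
             sigma = sigma, c_rand = cRand, l_rand = lRand,
             n_surrogates = nSurrogates, disconnected = disc)
}

#' Network metrics averaged over a threshold sweep
#'
#' Thresholds the matrix at each fraction, computes Cw, Lw and sigma per
#' network, and averages across the sweep (the per-threshold table is kept
#' alongside the summary means).
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param fractions density fractions (default the 25-35\% 1\%-step sweep).
#' @param nSurrogates surrogates per thresholded network (default 50).
#' @param swapsPerEdge swaps per edge (default 10).
#' @param seed integer seed; each threshold gets a child seed.
#' @return list with \code{perThreshold} (data.frame, one row per fraction)
#'   and \code{summary} (one-row data.frame of sweep means; threshold
#'   column is NA to mark the sweep mean).
#' @export
metricsOverSweep <- function(m, fractions = seq(0.25, 0.35, by = 0.01),
                             nSurrogates = 50L, swapsPerEdge = 10L, seed = 1L) {
  nets <- thresholdSweep(m, fractions)
  rows <- lapply(seq_along(nets), function(t)
    smallWorldSigma(nets[[t]], nSurrogates, swapsPerEdge,
                    childSeed(seed, 1000L + t)))
  perThreshold <- do.call(rbind, rows)
  summary <- data.frame(threshold = NA_real_,
                        Cw = mean(perThreshold$Cw),
                        Lw = mean(perThreshold$Lw),
                        sigma = mean(perThreshold$sigma),
                        c_rand = mean(perThreshold$c_rand),
                        l_rand = mean(perThreshold$l_rand),
                        n_surrogates = nSurrogates,
                        disconnected = any(perThreshold$disconnected))
  list(perThreshold = perThreshold, summary = summary)
}
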