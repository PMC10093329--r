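# shared fixtures and independent oracles for the test suite

# sinusoid recording: channels = list of function(t) -> amplitude
sineRecording <- function(freqs, seconds, fs, labels = NULL, phases = 0) {
  t <- seq_len(seconds * fs) / fs
  phases <- rep_len(phases, length(freqs))
  data <- t(mapply(function(f, ph) cos(2 * pi * f * t + ph), freqs, phases))
  if (is.null(labels)) labels <- paste0("ch", seq_along(freqs))
  EEGRecording(data, labels, fs)
}

# random symmetric PLI-like matrix with distinct entries in (0, 1)
randomConnectivity <- function(n, seed, labels = paste0("n", seq_len(n))) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0.01, 0.99)
  v <- v + t(v)
  ConnectivityMatrix(v, labels)
}

# random connected-ish weighted network on n nodes with m edges
randomNetwork <- function(n, m, seed) {
  set.seed(seed)
  all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- sample.int(nrow(all), m)
  edges <- data.frame(i = all[pick, 1], j = all[pick, 2],
                      weight = runif(m, 0.05, 1))
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  WeightedNetwork(paste0("n", seq_len(n)), edges, m / nrow(all))
}

netAsMatrix <- function(net) {
  n <- length(networkNodes(net))
  W <- matrix(0, n, n)
  e <- networkEdges(net)
  for (r in seq_len(nrow(e))) {
    W[e$i[r], e$j[r]] <- W[e$j[r], e$i[r]] <- e$weight[r]
  }
  W
}

# oracle: weighted clustering by direct enumeration of ordered triples
clusteringOracle <- function(net) {
  W <- netAsMatrix(net)
  A <- (W > 0) * 1
  n <- nrow(W)
  per <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == h || j == i || h == i) next
      tot <- tot + (W[i, j] + W[i, h]) / 2 * A[i, j] * A[i, h] * A[j, h]
    }
    per[i] <- tot / (sum(W[i, ]) * (k - 1))
  }
  list(perNode = per, mean = mean(per))
}

# oracle: exhaustive shortest paths on 1/w lengths by DFS over simple paths
pathLengthOracle <- function(net) {
  W <- netAsMatrix(net)
  n <- nrow(W)
  best <- matrix(Inf, n, n)
  dfs <- function(start, cur, visited, len) {
    if (len < best[start, cur]) best[start, cur] <<- len
    for (nxt in seq_len(n)) {
      if (W[cur, nxt] > 0 && !visited[nxt]) {
        v2 <- visited; v2[nxt] <- TRUE
        dfs(start, nxt, v2, len + 1 / W[cur, nxt])
      }
    }
  }
  for (s in seq_len(n)) {
    vis <- rep(FALSE, n); vis[s] <- TRUE
    dfs(s, s, vis, 0)
  }
  off <- best[upper.tri(best)]
  list(value = mean(off[is.finite(off)]), unreachable = sum(!is.finite(off)))
}

degSeq <- function(net) {
  e <- networkEdges(net)
  sort(tabulate(c(e$i, e$j), nbins = length(networkNodes(net))))
}

# interior (middle 80%) index range of a vector
interior <- function(x) {
  n <- length(x)
  (floor(n / 10) + 1):(n - floor(n / 10))
}

# circular difference of consecutive samples
circDiff <- function(p) atan2(sin(diff(p)), cos(diff(p)))

# P(wrap(lag + J) in (0, pi)) for J ~ vonMises(0, kappa), by numerical
# integration of the density (independent of the package's sampler)
vonMisesPliOracle <- function(lag, kappa) {
  dens <- function(x) exp(kappa * cos(x)) / (2 * pi * besselI(kappa, 0))
  # wrap(lag + J) in (0, pi) <=> J in (-lag, pi - lag) modulo 2pi
  lo <- -lag; hi <- pi - lag
  p <- stats::integrate(dens, lo, hi, rel.tol = 1e-9)$value
  abs(2 * p - 1)
}

# two-group subject-level PLI matrices (epoch means) from the synthetic
# generator, one rhythm band; subjects are iid draws, the regime where the
# classical one-way ANOVA holds its nominal level
subjectMatrices <- function(spec, band = "alpha1") {
  cfg <- defaultConfig(cohort = spec)
  cfg$bands <- rhythmBands()[band]
  out <- list(HGAD = list(), LGAD = list())
  for (g in c("LGAD", "HGAD")) {
    for (s in seq_len(spec$nSubjectsPerGroup[[g]])) {
      rec <- generateSubject(spec, g, s)
      conn <- plinet:::connectivityForRecording(rec, cfg)
      out[[g]] <- c(out[[g]], list(meanConnectivity(conn[[band]])))
    }
  }
  out
}

# identical coupling specs for both groups (global null)
sameGroupSpecs <- function() {
  bands <- rhythmBands()
  one <- list(couplingSpec(bands$theta), couplingSpec(bands$alpha1),
              couplingSpec(bands$alpha2), couplingSpec(bands$beta))
  list(LGAD = one, HGAD = one)
}
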