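triangleNet <- function() {
  WeightedNetwork(c("A", "B", "C"),
                  data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                             weight = c(0.5, 0.5, 1.0)), 1)
}

test_that("proportional threshold keeps the top fraction of edges", {
  m <- randomConnectivity(16, seed = 5, labels = canonicalMontage())
  net <- proportionalThreshold(m, 0.25)
  expect_equal(nrow(networkEdges(net)), 30)      # round(0.25 * 120)
  # retained edges are exactly the 30 largest weights
  v <- connectivityValues(m)
  top <- sort(v[upper.tri(v)], decreasing = TRUE)[1:30]
  expect_equal(sort(networkEdges(net)$weight, decreasing = TRUE), top)

  full <- proportionalThreshold(m, 1.0)
  expect_equal(nrow(networkEdges(full)), 120)

  m3 <- ConnectivityMatrix(matrix(c(0, .9, .5, .9, 0, .1, .5, .1, 0), 3),
                           c("A", "B", "C"))
  one <- proportionalThreshold(m3, 1 / 3)
  expect_equal(networkEdges(one),
               data.frame(i = 1L, j = 2L, weight = 0.9))
  expect_error(proportionalThreshold(m, 0), "fraction")
  expect_error(proportionalThreshold(m, 1.2), "fraction")
})

test_that("the default threshold sweep yields 11 nested networks", {
  m <- randomConnectivity(16, seed = 6, labels = canonicalMontage())
  nets <- thresholdSweep(m)
  expect_length(nets, 11)
  expect_equal(vapply(nets, function(n) nrow(networkEdges(n)), 0L),
               plinet:::roundHalfUp(seq(0.25, 0.35, 0.01) * 120))
  two <- thresholdSweep(m, c(0.25, 0.35))
  expect_equal(vapply(two, function(n) nrow(networkEdges(n)), 0L), c(30L, 42L))
  # nested: edges at 25% are a subset of edges at 35% (all weights distinct)
  key <- function(n) paste(networkEdges(n)$i, networkEdges(n)$j)
  expect_true(all(key(two[[1]]) %in% key(two[[2]])))
  expect_error(thresholdSweep(m, numeric(0)), "empty")
})

test_that("weighted clustering matches hand values on canonical fixtures", {
  # complete triangle saturates the normalisation whatever the weights
  allOne <- WeightedNetwork(c("A", "B", "C"),
    data.frame(i = c(1, 1, 2), j = c(2, 3, 3), weight = c(1, 1, 1)), 1)
  expect_equal(weightedClustering(allOne)$perNode,
               c(A = 1, B = 1, C = 1))
  expect_equal(weightedClustering(triangleNet())$mean, 1)
  # no closed triple -> zero everywhere
  path3 <- WeightedNetwork(c("A", "B", "C"),
    data.frame(i = c(1, 2), j = c(2, 3), weight = c(0.7, 0.2)), NA)
  expect_equal(weightedClustering(path3)$mean, 0)
  expect_error(weightedClustering(WeightedNetwork("A", data.frame(
    i = integer(0), j = integer(0), weight = numeric(0)))), "empty")
})

test_that("weighted path length matches hand values and flags disconnection", {
  pair <- WeightedNetwork(c("A", "B"),
    data.frame(i = 1, j = 2, weight = 0.5), NA)
  expect_equal(weightedPathLength(pair)$value, 2)
  tri <- weightedPathLength(triangleNet())
  expect_equal(tri$value, 5 / 3)   # lengths 2, 2, 1; detour 3 never shortcuts
  expect_false(tri$disconnected)
  iso <- WeightedNetwork(c("A", "B", "C"),
    data.frame(i = 1, j = 2, weight = 0.5), NA)
  pl <- weightedPathLength(iso)
  expect_true(pl$disconnected)
  expect_equal(pl$unreachablePairs, 2)
  expect_equal(pl$value, 2)        # mean over the one reachable pair
})

test_that("clustering and path length agree with exhaustive oracles", {
  for (seed in 1:60) {
    n <- sample(4:6, 1)
    net <- randomNetwork(n, sample(3:(n * (n - 1) / 2), 1), seed)
    expect_equal(weightedClustering(net)$perNode,
                 clusteringOracle(net)$perNode, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(weightedPathLength(net)$value,
                 pathLengthOracle(net)$value, tolerance = 1e-12)
  }
})

test_that("clustering agrees with the independent igraph Barrat implementation", {
  for (seed in 101:115) {
    net <- randomNetwork(7, 12, seed)
    e <- networkEdges(net)
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$i, to = e$j, weight = e$weight),
      directed = FALSE, vertices = data.frame(name = 1:7))
    ig <- igraph::transitivity(g, type = "barrat", isolates = "zero")
    ours <- weightedClustering(net)$perNode
    deg <- tabulate(c(e$i, e$j), 7)
    expect_equal(unname(ours[deg >= 2]), unname(ig[deg >= 2]),
                 tolerance = 1e-10)
  }
})

test_that("equal weights reduce to binary clustering and scaled binary path length", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 7
    base <- randomNetwork(n, 12, 200 + rep)
    w <- runif(1, 0.2, 0.9)
    e <- networkEdges(base); e$weight <- w
    net <- WeightedNetwork(networkNodes(base), e, NA)
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$i, to = e$j), directed = FALSE,
      vertices = data.frame(name = 1:n))
    binC <- igraph::transitivity(g, type = "local", isolates = "zero")
    deg <- tabulate(c(e$i, e$j), n)
    ours <- weightedClustering(net)$perNode
    expect_equal(unname(ours[deg >= 2]), unname(binC[deg >= 2]),
                 tolerance = 1e-10)
    binL <- mean(igraph::distances(g)[upper.tri(diag(n))])
    if (is.finite(binL))
      expect_equal(weightedPathLength(net)$value, binL / w, tolerance = 1e-10)
  }
})

test_that("per-node weighted clustering stays in [0, 1] on random graphs", {
  for (seed in 1:300) {
    n <- sample(4:10, 1)
    maxE <- n * (n - 1) / 2
    net <- randomNetwork(n, sample(3:maxE, 1), 5000 + seed)
    cc <- weightedClustering(net)$perNode
    expect_true(all(cc >= 0 & cc <= 1 + 1e-12))
  }
})

test_that("Maslov-Sneppen rewiring preserves all conserved quantities", {
  net <- randomNetwork(16, 36, 77)
  for (s in 1:5) {
    sur <- maslovSneppenRewire(net, swapsPerEdge = 10, seed = s)
    expect_identical(networkNodes(sur), networkNodes(net))
    expect_equal(nrow(networkEdges(sur)), nrow(networkEdges(net)))
    expect_equal(degSeq(sur), degSeq(net))
    expect_equal(sort(networkEdges(sur)$weight),
                 sort(networkEdges(net)$weight))
    e <- networkEdges(sur)
    expect_true(all(e$i < e$j))
    expect_equal(anyDuplicated(e[, c("i", "j")]), 0L)
  }
  # topology actually changes on a rewireable graph
  sur <- maslovSneppenRewire(net, 10, seed = 3)
  expect_false(identical(networkEdges(sur)[, c("i", "j")],
                         networkEdges(net)[, c("i", "j")]))
  # determinism
  expect_identical(maslovSneppenRewire(net, 10, seed = 9),
                   maslovSneppenRewire(net, 10, seed = 9))
})

test_that("a 3-node path admits no valid swap and is returned unchanged", {
  path3 <- WeightedNetwork(c("A", "B", "C"),
    data.frame(i = c(1, 2), j = c(2, 3), weight = c(0.4, 0.8)), NA)
  expect_warning(sur <- maslovSneppenRewire(path3, 2, seed = 1), "unchanged")
  expect_equal(networkEdges(sur), networkEdges(path3))
  expect_true(attr(sur, "rewireExhausted"))
})

test_that("sigma is 1 for an equal-weight complete graph and is seed-reproducible", {
  n <- 6
  all <- which(upper.tri(diag(n)), arr.ind = TRUE)
  complete <- WeightedNetwork(paste0("n", 1:n),
    data.frame(i = all[, 1], j = all[, 2], weight = 0.6), 1)
  # a complete graph admits no valid swap; the rewire warning is expected
  met <- suppressWarnings(smallWorldSigma(complete, nSurrogates = 4, seed = 2))
  expect_equal(met$sigma, 1)
  expect_equal(met$Cw, 1)           # every surrogate is the same graph

  # planted two-block matrix: deterministic re-run reproduces sigma exactly
  v <- matrix(0.1, 16, 16)
  v[1:8, 1:8] <- 0.8; v[9:16, 9:16] <- 0.7
  v[lower.tri(v)] <- t(v)[lower.tri(v)]; diag(v) <- 0
  set.seed(19); v[upper.tri(v)] <- v[upper.tri(v)] + runif(120, 0, 0.01)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  m <- ConnectivityMatrix(v, canonicalMontage())
  net <- proportionalThreshold(m, 0.3)
  a <- smallWorldSigma(net, nSurrogates = 50, seed = 1234)
  b <- smallWorldSigma(net, nSurrogates = 50, seed = 1234)
  expect_identical(a, b)
  expect_gt(a$sigma, 1)             # block structure clusters above random
})

test_that("doubling the surrogate count moves sigma within sampling error", {
  v <- matrix(0.1, 16, 16)
  v[1:8, 1:8] <- 0.8
  v[lower.tri(v)] <- t(v)[lower.tri(v)]; diag(v) <- 0
  set.seed(91); v[upper.tri(v)] <- v[upper.tri(v)] + runif(120, 0, 0.02)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  net <- proportionalThreshold(ConnectivityMatrix(v, canonicalMontage()), 0.3)
  m1 <- smallWorldSigma(net, nSurrogates = 25, seed = 7)
  m2 <- smallWorldSigma(net, nSurrogates = 50, seed = 8)
  # surrogate-mean standard error, propagated through the sigma ratio
  crs <- vapply(1:25, function(s) weightedClustering(
    maslovSneppenRewire(net, 10, childSeed(7, s)))$mean, 0)
  se <- sd(crs) / sqrt(25) * m1$sigma / m1$c_rand
  expect_lt(abs(m1$sigma - m2$sigma), 3 * se + 1e-8)
})

test_that("sweep metrics average the per-threshold table", {
  m <- randomConnectivity(16, seed = 40, labels = canonicalMontage())
  sw <- metricsOverSweep(m, nSurrogates = 3, seed = 5)
  expect_equal(nrow(sw$perThreshold), 11)
  for (col in c("Cw", "Lw", "sigma", "c_rand", "l_rand"))
    expect_equal(sw$summary[[col]], mean(sw$perThreshold[[col]]))
  # single-fraction sweep equals a direct single call
  one <- metricsOverSweep(m, fractions = 0.30, nSurrogates = 3, seed = 5)
  direct <- smallWorldSigma(proportionalThreshold(m, 0.30), 3,
                            seed = childSeed(5, 1001))
  expect_equal(one$summary$Cw, direct$Cw)
  expect_equal(one$summary$Lw, direct$Lw)
  expect_equal(one$summary$sigma, direct$sigma)
})
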