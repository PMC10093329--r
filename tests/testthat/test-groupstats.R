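test_that("one-way ANOVA matches hand sums of squares and the t-test identity", {
  an <- onewayAnova(c(1, 2, 3), c(2, 3, 4))
  expect_equal(an$F, 1.5)            # SSB = 1.5, MSW = 1
  expect_equal(an$df, c(1, 4))
  # identical groups: no between-group variance
  same <- onewayAnova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # F equals squared pooled-variance t, p-values agree
  set.seed(3)
  for (rep in 1:50) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = runif(1, 0, 2))
    an <- onewayAnova(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(an$F - unname(tt$statistic)^2), 1e-9)
    expect_lt(abs(an$p - tt$p.value), 1e-12)
    expect_gte(an$F, 0)
    expect_true(an$p >= 0 && an$p <= 1)
  }
  # degenerate cases
  expect_error(onewayAnova(1, c(1, 2)), "at least 2")
  deg <- onewayAnova(c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
  sep <- onewayAnova(c(1, 1), c(2, 2))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
})

test_that("edgewise comparison tests every electrode pair with directions from means", {
  set.seed(17)
  mk <- function(shift) replicate(6, {
    v <- matrix(0, 4, 4)
    v[upper.tri(v)] <- pmin(pmax(runif(6, .3, .6) + shift, 0), 1)
    v <- v + t(v)
    ConnectivityMatrix(v, paste0("c", 1:4), band = "alpha2")
  }, simplify = FALSE)
  comp <- edgewiseComparison(mk(0.2), mk(0))
  er <- edgeResults(comp)
  expect_equal(nrow(er), 6)
  expect_identical(er[, c("i", "j")],
                   data.frame(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                              j = c(2L, 3L, 4L, 3L, 4L, 4L)))
  expect_equal(comp@band, "alpha2")
  expect_true(all(er$direction == "HGAD_higher"))   # shifted group is higher
  expect_true(all(er$significant == (er$p < 0.05)))
  # canonical montage -> 120 rows
  m16 <- function(s) lapply(1:3, function(k)
    randomConnectivity(16, seed = s * 10 + k, labels = canonicalMontage()))
  expect_equal(nrow(edgeResults(edgewiseComparison(m16(1), m16(2)))), 120)
  # montage mismatch
  bad <- list(randomConnectivity(4, 1), randomConnectivity(4, 2))
  expect_error(edgewiseComparison(bad,
    list(randomConnectivity(5, 3), randomConnectivity(5, 4))), "montage|length")
  expect_error(edgewiseComparison(bad[1], bad), "at least 2")
})

test_that("direction labels always agree with group sample means", {
  set.seed(29)
  a <- lapply(1:4, function(k) randomConnectivity(5, 300 + k))
  b <- lapply(1:4, function(k) randomConnectivity(5, 400 + k))
  er <- edgeResults(edgewiseComparison(a, b))
  va <- sapply(a, function(m) connectivityValues(m)[cbind(er$i, er$j)])
  vb <- sapply(b, function(m) connectivityValues(m)[cbind(er$i, er$j)])
  expect_identical(er$direction,
                   ifelse(rowMeans(va) >= rowMeans(vb),
                          "HGAD_higher", "LGAD_higher"))
})

test_that("Benjamini-Hochberg switch thins the significant set", {
  set.seed(71)
  a <- lapply(1:8, function(k) randomConnectivity(16, 500 + k,
                                                  canonicalMontage()))
  b <- lapply(1:8, function(k) randomConnectivity(16, 600 + k,
                                                  canonicalMontage()))
  raw <- edgeResults(edgewiseComparison(a, b))
  bh <- edgeResults(edgewiseComparison(a, b, adjust = "BH"))
  expect_lte(sum(bh$significant), sum(raw$significant))
  expect_equal(bh$p, raw$p)   # adjustment gates significance, not p itself
})

test_that("frontal summary counts edges with at least one frontal endpoint", {
  mkComp <- function(edges, dirs = rep("HGAD_higher", nrow(edges))) {
    er <- data.frame(i = rep(1L, nrow(edges)), j = rep(2L, nrow(edges)),
                     node_i = edges$a, node_j = edges$b,
                     F = rep(5, nrow(edges)), p = rep(0.01, nrow(edges)),
                     direction = dirs, significant = rep(TRUE, nrow(edges)))
    # pad with an insignificant non-frontal row so the montage holds labels
    er <- rbind(er, data.frame(i = 1L, j = 2L, node_i = "O1", node_j = "O2",
                               F = 0.1, p = 0.9, direction = "LGAD_higher",
                               significant = FALSE))
    methods::new("GroupComparison", band = "theta", unit = "epoch",
                 edgeResults = er, metricResults = data.frame(), alpha = 0.05)
  }
  s <- frontalSummary(mkComp(data.frame(a = c("FP1", "O1"), b = c("O1", "O2"))),
                      frontal = "FP1")
  expect_equal(s$n_significant_edges, 2)
  expect_equal(s$n_frontal_related, 1)
  expect_equal(s$frontal_fraction, 0.5)
  expect_equal(s$n_increased_in_HGAD, 2)
  # all-frontal case
  allf <- frontalSummary(mkComp(data.frame(a = c("F3", "F4"), b = c("F4", "F7"))),
                         frontal = c("F3", "F4", "F7"))
  expect_equal(allf$frontal_fraction, 1)
  # empty case: no significant edges
  none <- mkComp(data.frame(a = character(0), b = character(0)))
  s0 <- frontalSummary(none, frontal = character(0))
  expect_equal(s0$n_significant_edges, 0)
  expect_true(is.na(s0$frontal_fraction))
  # frontal label absent from montage
  expect_error(frontalSummary(none, c("FP1", "FZ")), "FZ")
})

test_that("frontal fraction is invariant to edge-row order", {
  set.seed(83)
  a <- lapply(1:4, function(k) randomConnectivity(16, 700 + k,
                                                  canonicalMontage()))
  b <- lapply(1:4, function(k) randomConnectivity(16, 800 + k,
                                                  canonicalMontage()))
  comp <- edgewiseComparison(a, b, alpha = 0.3)
  shuffled <- comp
  shuffled@edgeResults <- comp@edgeResults[sample.int(120), ]
  expect_equal(frontalSummary(shuffled)$frontal_fraction,
               frontalSummary(comp)$frontal_fraction)
})

test_that("metric-wise comparison flags a planted strong shift and needs n >= 2", {
  set.seed(47)
  mk <- function(n, shift = 0) data.frame(Cw = rnorm(n, 0.5 + shift, 0.05),
                                          Lw = rnorm(n, 3 + shift, 0.05),
                                          sigma = rnorm(n, 1 + shift, 0.05))
  hits <- replicate(20, {
    comp <- metricwiseComparison(mk(50, shift = 0.25), mk(50), band = "beta")
    all(metricResults(comp)$significant)
  })
  expect_gt(mean(hits), 0.95)     # 5-sd shift at n = 50: power ~ 1
  mr <- metricResults(metricwiseComparison(mk(10, 0.25), mk(10)))
  expect_equal(mr$metric, c("Cw", "Lw", "sigma"))
  expect_true(all(mr$mean_HGAD > mr$mean_LGAD))
  expect_error(metricwiseComparison(mk(1), mk(5)), "at least 2")
})

test_that("metric-wise nulls reject at about the alpha rate", {
  set.seed(59)
  mk <- function(n) data.frame(Cw = rnorm(n, 0.5, 0.05),
                               Lw = rnorm(n, 3, 0.2),
                               sigma = rnorm(n, 1, 0.1))
  ps <- replicate(400, metricResults(
    metricwiseComparison(mk(12), mk(12)))$p[1])
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)           # 3 binomial SEs around 0.05 at 400 draws
})
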