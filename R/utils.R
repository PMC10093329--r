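#' @importFrom methods new validObject is slot
#' @importFrom stats fft runif rnorm sd
NULL

# round-half-up: round(0.5)=0 under R's banker's rounding, edge counts need 0.5 -> 1
roundHalfUp <- function(x) floor(x + 0.5)

#' Derive a child seed from a parent seed and a counter
#'
#' Stochastic operations (surrogate generation, per-subject simulation) take
#' one explicit seed and derive independent child seeds for their internal
#' replicates with this fixed affine-mod scheme, so a whole run is a pure
#' function of its master seed.
#'
#' @param seed integer parent seed.
#' @param i non-negative integer counter.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
childSeed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  as.integer((as.double(seed) * 69621 + as.double(i) * 10007 + 1) %% 2147483647)
}

# evaluate expr under a fixed RNG seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}

# von Mises(mu, kappa) sampler, Best & Fisher (1979) wrapped-Cauchy rejection.
# kappa = 0 -> uniform on (-pi, pi]; kappa = Inf -> point mass at mu.
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) {
    th <- runif(n, -pi, pi)
    return(wrapPhase(th + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  k <- 0L
  while (k < n) {
    m <- n - k
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(sum(ok), n - k)
      out[(k + 1L):(k + take)] <- th[seq_len(take)]
      k <- k + take
    }
  }
  wrapPhase(out + mu)
}

# wrap angles to (-pi, pi]
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Canonical 16-electrode montage of the international 10-20 system
#'
#' The default scalp montage, in its canonical printed order; this order is
#' the node index order used throughout the package.
#'
#' @return character vector of 16 electrode labels.
#' @export
canonicalMontage <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
}

#' Frontal electrodes of the canonical montage
#'
#' @return character vector of the six frontal labels.
#' @export
frontalElectrodes <- function() c("FP1", "FP2", "F3", "F4", "F7", "F8")

#' Canonical EEG rhythm bands
#'
#' Theta 4-8 Hz, alpha1 8-10 Hz, alpha2 10-13 Hz, beta 13-30 Hz.
#'
#' @return named list of length-2 numeric vectors c(low_hz, high_hz).
#' @export
rhythmBands <- function() {
  list(theta = c(4, 8), alpha1 = c(8, 10), alpha2 = c(10, 13), beta = c(13, 30))
}

# validate one band spec: c(low, high) with 0 < low < high
checkBand <- function(band) {
  if (!is.numeric(band) || length(band) != 2L || anyNA(band))
    stop("a rhythm band must be a numeric c(low_hz, high_hz)")
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("rhythm band must satisfy 0 < low_hz < high_hz, got (",
         band[1], ", ", band[2], ")")
  invisible(band)
}
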