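# Independent brute-force oracles for the threshold criteria. These are
# deliberately naive re-derivations (explicit sums over the full grey axis,
# linear-system / polynomial-root solutions) kept free of the package's
# cumulative-sum implementations.

newHist <- function(counts) {
  new("IntensityHistogram", counts = as.numeric(counts), total = sum(counts))
}

oracleHuangScan <- function(counts) {
  occ <- range(which(counts > 0)) - 1L
  C <- occ[2L] - occ[1L]
  g <- 0:255
  Hf <- function(u) ifelse(u > 0 & u < 1, -u * log(u) - (1 - u) * log(1 - u), 0)
  cand <- occ[1L]:(occ[2L] - 1L)
  S <- vapply(cand, function(t) {
    i0 <- g <= t
    mu0 <- sum(g[i0] * counts[i0]) / sum(counts[i0])
    mu1 <- sum(g[!i0] * counts[!i0]) / sum(counts[!i0])
    u <- ifelse(i0, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    sum(counts * Hf(u))
  }, numeric(1L))
  cand[which.min(S)]
}

oracleLiScan <- function(counts) {
  g <- 0:255
  eps <- 1e-10
  occ <- range(which(counts > 0)) - 1L
  cand <- occ[1L]:(occ[2L] - 1L)
  eta <- vapply(cand, function(t) {
    i0 <- g <= t
    A0 <- sum(g[i0] * counts[i0]); n0 <- sum(counts[i0])
    A1 <- sum(g[!i0] * counts[!i0]); n1 <- sum(counts[!i0])
    mu0 <- max(if (n0 > 0) A0 / n0 else 0, eps)
    mu1 <- max(if (n1 > 0) A1 / n1 else 0, eps)
    -(A0 * log(mu0) + A1 * log(mu1))
  }, numeric(1L))
  cand[which.min(eta)]
}

oracleMomentsSolve <- function(counts) {
  p <- counts / sum(counts)
  g <- 0:255
  m <- vapply(1:3, function(k) sum(g^k * p), numeric(1L))
  A <- rbind(c(1, m[1L]), c(m[1L], m[2L]))
  cf <- -solve(A, c(m[2L], m[3L]))          # z^2 + cf[2] z + cf[1] = 0
  z <- sort(Re(polyroot(c(cf[1L], cf[2L], 1))))
  p0 <- (z[2L] - m[1L]) / (z[2L] - z[1L])
  which(cumsum(p) >= p0 - 1e-12)[1L] - 1L
}

# random two-Gaussian mixture histogram (the canonical thresholding input)
randomMixtureCounts <- function() {
  m1 <- runif(1, 20, 110); m2 <- runif(1, 130, 240)
  s1 <- runif(1, 5, 30); s2 <- runif(1, 5, 30)
  w <- runif(1, 0.2, 0.8)
  g <- 0:255
  floor(0.5 + 4000 * (w * dnorm(g, m1, s1) + (1 - w) * dnorm(g, m2, s2)) +
        sample(0:2, 256, replace = TRUE))
}

# ---- shape fixtures -------------------------------------------------------

maskSquare <- function(side, pad = 5L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

maskDisk <- function(r, pad = 6L) {
  n <- 2L * r + 2L * pad
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2) <= r^2
}

maskRect <- function(w, h, pad = 6L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- TRUE
  m
}

maskEllipse <- function(a, b, theta, pad = 6L) {
  n <- 2L * ceiling(a) + 2L * pad
  c0 <- (n + 1) / 2
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  X <- (i - c0) * cos(theta) + (j - c0) * sin(theta)
  Y <- -(i - c0) * sin(theta) + (j - c0) * cos(theta)
  (X / a)^2 + (Y / b)^2 <= 1
}

ellipsePerimeter <- function(a, b, n = 2e5) {
  tt <- seq(0, 2 * pi, length.out = n + 1)
  x <- a * cos(tt); y <- b * sin(tt)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# tiny deterministic stack: linear exposure response g*e, clipped to 8 bits
linearStack <- function(gain, exposures, dims = c(12L, 10L), ps = 0.8) {
  frames <- lapply(exposures, function(e) {
    v <- matrix(pmin(255, floor(0.5 + gain * e * seq_len(prod(dims)) /
                                  prod(dims))), dims[1L], dims[2L])
    GreyImage(v, ps)
  })
  ExposureStack(frames, exposures)
}
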