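#' @name thresholds
#' @title Automatic histogram thresholds of the wood-section procedure
#'
#' @description
#' The automated procedure selects four classical 256-bin histogram
#' thresholds, used with dark-background polarity: Huang's fuzzy-entropy
#' threshold and Tsai's moment-preserving threshold for the cell-wall mask
#' (spruce and beechwood respectively), and Li's minimum-cross-entropy
#' threshold and Prewitt's iterated-smoothing "Minimum" threshold for the
#' lumen mask. All four operate on an [IntensityHistogram-class] and return
#' a [ThresholdResult-class].
#'
#' Common conventions: candidate levels are restricted to the occupied grey
#' range; criterion ties are broken toward the lower level (determinism
#' across platforms); a histogram whose mass sits on a single level returns
#' that level with the `degenerate` flag set instead of erroring, so batch
#' runs survive blank fields of view. Thresholds are invariant to uniform
#' scaling of the counts.
#'
#' @param hist an [IntensityHistogram-class].
#' @return a [ThresholdResult-class]; pixels strictly above the level are
#'   foreground under the dark-background convention (see
#'   [applyThreshold()]).
NULL

# occupied level range (0-based grey levels)
occupiedRange <- function(counts) {
  occ <- which(counts > 0) - 1L
  c(min(occ), max(occ))
}

degenerateResult <- function(counts, method) {
  lev <- which(counts > 0)[1L] - 1L
  new("ThresholdResult", level = as.integer(lev), method = method,
      darkBackground = TRUE, degenerate = TRUE)
}

# Shannon entropy of a fuzzy membership value, 0*log0 := 0
fuzzyEntropy <- function(u) {
  h <- numeric(length(u))
  i <- u > 0 & u < 1
  h[i] <- -u[i] * log(u[i]) - (1 - u[i]) * log(1 - u[i])
  h
}

#' @rdname thresholds
#' @details `thresholdHuang()` minimises the Huang--Wang fuzzy-membership
#' entropy: for a candidate level t the two classes get their mean grey
#' levels as prototypes, each pixel's membership is
#' `1 / (1 + |g - mu_class| / C)` with `C` the occupied grey range, and the
#' level with minimal total Shannon entropy of the memberships is returned.
#' @export
thresholdHuang <- function(hist) {
  counts <- hist@counts
  rng <- occupiedRange(counts)
  if (rng[1L] == rng[2L]) return(degenerateResult(counts, "huang"))
  g <- 0:255
  C <- rng[2L] - rng[1L]
  cw <- cumsum(counts)           # class-0 pixel count up to level t
  cm <- cumsum(g * counts)       # class-0 intensity mass
  tot <- hist@total
  totm <- cm[256L]
  cand <- rng[1L]:(rng[2L] - 1L)
  S <- vapply(cand, function(t) {
    i0 <- 1L:(t + 1L); i1 <- (t + 2L):256L
    mu0 <- cm[t + 1L] / cw[t + 1L]
    mu1 <- (totm - cm[t + 1L]) / (tot - cw[t + 1L])
    u0 <- 1 / (1 + abs(g[i0] - mu0) / C)
    u1 <- 1 / (1 + abs(g[i1] - mu1) / C)
    sum(counts[i0] * fuzzyEntropy(u0)) + sum(counts[i1] * fuzzyEntropy(u1))
  }, numeric(1L))
  lev <- cand[which.min(S)]      # which.min takes the first (lowest) tie
  new("ThresholdResult", level = as.integer(lev), method = "huang",
      darkBackground = TRUE, degenerate = FALSE)
}

#' @rdname thresholds
#' @details `thresholdLi()` computes the minimum-cross-entropy threshold by
#' the Li--Tam fixed-point iteration: starting from the histogram mean, the
#' next level is `(mu0 - mu1) / (log mu0 - log mu1)` with `mu0`, `mu1` the
#' class mean grey levels at the current level, iterated until the rounded
#' level stops changing (change < 0.5). Because rounding the continuous
#' fixed point can land one level off the discrete optimum, the result is
#' slid to the adjacent minimum of the cross-entropy objective, making the
#' returned level the minimiser of the published criterion. Class means of
#' zero are floored at a small epsilon so histograms with mass at grey
#' level 0 remain defined.
#' @export
thresholdLi <- function(hist) {
  counts <- hist@counts
  rng <- occupiedRange(counts)
  if (rng[1L] == rng[2L]) return(degenerateResult(counts, "li"))
  g <- 0:255
  cw <- cumsum(counts); cm <- cumsum(g * counts)
  tot <- cw[256L]; totm <- cm[256L]
  eps <- 1e-10
  # cross-entropy objective at integer level t (class 0 = levels <= t)
  eta <- function(t) {
    A0 <- cm[t + 1L]; n0 <- cw[t + 1L]
    A1 <- totm - A0; n1 <- tot - n0
    mu0 <- max(if (n0 > 0) A0 / n0 else 0, eps)
    mu1 <- max(if (n1 > 0) A1 / n1 else 0, eps)
    -(A0 * log(mu0) + A1 * log(mu1))
  }
  t <- roundHalfUp(totm / tot)
  t <- min(max(t, rng[1L]), rng[2L] - 1L)
  seen <- logical(256L)
  for (iter in 1:256) {
    mu0 <- max(cm[t + 1L] / max(cw[t + 1L], eps), eps)
    mu1 <- max((totm - cm[t + 1L]) / max(tot - cw[t + 1L], eps), eps)
    tNew <- roundHalfUp((mu0 - mu1) / (log(mu0) - log(mu1)))
    tNew <- min(max(tNew, rng[1L]), rng[2L] - 1L)
    if (abs(tNew - t) < 0.5) { t <- tNew; break }
    if (seen[tNew + 1L]) { t <- min(t, tNew); break }  # 2-cycle: lower level
    seen[t + 1L] <- TRUE
    t <- tNew
  }
  # discretization refinement: descend to the neighbouring local minimum of
  # the objective (ties toward the lower level)
  repeat {
    if (t > rng[1L] && eta(t - 1L) <= eta(t)) { t <- t - 1L; next }
    if (t < rng[2L] - 1L && eta(t + 1L) < eta(t)) { t <- t + 1L; next }
    break
  }
  new("ThresholdResult", level = as.integer(t), method = "li",
      darkBackground = TRUE, degenerate = FALSE)
}

#' @rdname thresholds
#' @details `thresholdMoments()` is Tsai's moment-preserving threshold: the
#' first three grey-level moments of the image determine a two-level image
#' with identical moments; its background fraction `p0` is computed in closed
#' form and the threshold is the smallest level at which the cumulative
#' histogram fraction reaches `p0`.
#' @export
thresholdMoments <- function(hist) {
  counts <- hist@counts
  rng <- occupiedRange(counts)
  if (rng[1L] == rng[2L]) return(degenerateResult(counts, "moments"))
  p <- counts / hist@total
  g <- 0:255
  m1 <- sum(g * p); m2 <- sum(g^2 * p); m3 <- sum(g^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (!is.finite(disc) || disc <= 0 || cd <= 0)
    return(degenerateResult(counts, "moments"))
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cf <- cumsum(p)
  lev <- which(cf >= p0 - 1e-12)[1L] - 1L
  lev <- min(max(lev, rng[1L]), rng[2L])
  new("ThresholdResult", level = as.integer(lev), method = "moments",
      darkBackground = TRUE, degenerate = FALSE)
}

# one pass of the 3-bin mean filter; edge bins average the two available
# bins (the bin itself and its single neighbour)
smoothHistogram <- function(h) {
  n <- length(h)
  s <- (c(h[1L], h[-n]) + h + c(h[-1L], h[n])) / 3
  s[1L] <- (h[1L] + h[2L]) / 2
  s[n] <- (h[n - 1L] + h[n]) / 2
  s
}

countPeaks <- function(h) {
  n <- length(h)
  i <- 2:(n - 1L)
  which(h[i] > h[i - 1L] & h[i] > h[i + 1L]) + 1L
}

#' @rdname thresholds
#' @details `thresholdMinimum()` iteratively smooths the 256-bin histogram
#' with a 3-bin mean filter (edge bins averaged over the two available bins)
#' until exactly two local maxima remain, then returns the level of the
#' minimum between them (ties toward the lower level). A histogram that
#' never becomes bimodal raises an error naming the iteration cap.
#' @param maxIter iteration cap for `thresholdMinimum()` (default 10000).
#' @export
thresholdMinimum <- function(hist, maxIter = 10000L) {
  counts <- hist@counts
  rng <- occupiedRange(counts)
  if (rng[1L] == rng[2L]) return(degenerateResult(counts, "minimum"))
  h <- counts
  for (iter in seq_len(maxIter)) {
    h <- smoothHistogram(h)
    pk <- countPeaks(h)
    if (length(pk) == 2L) {
      between <- (pk[1L] + 1L):(pk[2L] - 1L)
      lev <- between[which.min(h[between])] - 1L
      return(new("ThresholdResult", level = as.integer(lev),
                 method = "minimum", darkBackground = TRUE,
                 degenerate = FALSE))
    }
    # fewer than 2 strict maxima can be a transient plateau of the mean
    # filter; keep smoothing until the cap
  }
  stop(sprintf(paste0("histogram did not become bimodal within the ",
                      "iteration cap of %d smoothing passes"),
               maxIter), call. = FALSE)
}

#' Run a named threshold method
#'
#' Dispatches on the method names used in configuration files and on the
#' command line: `"huang"`, `"li"`, `"moments"`, `"minimum"` (all applied
#' with dark-background polarity, mirroring the "Huang dark", "Li dark",
#' "Moments dark" and "Minimum" selections of the procedure).
#'
#' @param hist an [IntensityHistogram-class].
#' @param method method name.
#' @param ... passed to the method (e.g. `maxIter` for `"minimum"`).
#' @return a [ThresholdResult-class].
#' @export
autoThreshold <- function(hist, method, ...) {
  switch(match.arg(method, c("huang", "li", "moments", "minimum")),
         huang = thresholdHuang(hist),
         li = thresholdLi(hist),
         moments = thresholdMoments(hist),
         minimum = thresholdMinimum(hist, ...))
}

#' Binarize an image at a threshold level
#'
#' With dark-background polarity the bright cell walls are the pixels
#' strictly above the level (`select = "above"`); the dark lumens are the
#' pixels at or below it (`select = "at_or_below"`). The two selections
#' partition the image exactly.
#'
#' @param image a [GreyImage-class].
#' @param result a [ThresholdResult-class] (or a bare integer level).
#' @param select `"above"` or `"at_or_below"`.
#' @return logical matrix of the image's dimensions.
#' @export
applyThreshold <- function(image, result, select = c("above", "at_or_below")) {
  select <- match.arg(select)
  lev <- if (is(result, "ThresholdResult")) result@level else as.integer(result)
  assertThat(lev >= 0L && lev <= 255L, "level must lie in [0, 255]")
  if (select == "above") image@pixels > lev else image@pixels <= lev
}
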