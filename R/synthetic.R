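#' Construct a synthetic-section specification
#'
#' Builds a [SectionSpec-class] with species shape defaults chosen to emulate
#' the two reference tissues: `"spruce"` lays tracheid lumens (rounded
#' rectangles with lognormal size spread) on a jittered heterogeneous grid
#' separated by autofluorescent walls; `"beechwood"` scatters large vessel
#' lumens (ellipses, lognormal equivalent radius) by dart throwing among a
#' bed of small sub-threshold fibre lumens, so the species size filter is
#' exercised exactly as in the real procedure. Acquisition defaults follow
#' the reference protocol: 0.8 um/px, exposures 100--3000 ms in 100 ms
#' steps, 8-bit clipping. Severity drives radial shrinkage, boundary
#' deformation (low-order harmonic perturbation of each lumen outline) and
#' wall-fluorescence loss simultaneously, mirroring the joint morphological
#' and chemical effect of harsher pretreatment.
#'
#' @param speciesMode `"spruce"` or `"beechwood"`.
#' @param nCells target lumen count (tracheids / vessels).
#' @param seed integer RNG seed; the full section is reproducible from it.
#' @param pixelSizeUm micrometres per pixel.
#' @param exposuresMs exposure series in ms.
#' @param severity deformation severity in \[0, 1\].
#' @param sizeScale multiplier on lumen linear dimensions.
#' @param wallGain wall fluorescence gain (grey levels per ms at severity 0);
#'   the default reproduces an untreated hardwood wall (~23.4 grey at
#'   2000 ms).
#' @param lumenGainFrac lumen background gain as a fraction of wall gain.
#' @param noiseSd Gaussian sensor noise sd (grey levels).
#' @param illuminationAmplitude relative amplitude of the smooth
#'   multiplicative illumination field ("wavy section" inhomogeneity).
#' @param edgeSoftnessPx width of the wall/lumen transition ramp (px).
#' @param imageSizePx integer `(width, height)`, or `NA` (default) to size
#'   the image from the layout.
#' @param shape named list of overrides of the species shape defaults (see
#'   Details).
#' @details Shape defaults (overridable via `shape`): spruce —
#'   `meanLumenPx` 25.4 (mean lumen pitch, px), `sizeSdLog` 0.29 (lognormal
#'   sd of row/column pitches), `fillMin`/`fillMax` 0.80/0.95 (lumen fill
#'   fraction of its cell), `wallPx` 5, `cornerRadiusFrac` 0.30, `ampMax`
#'   0.45 (total harmonic amplitude at severity 1), `harmonics` 2:6,
#'   `shrinkMax` 0.30, `jitterPx` 1.5, `thetaJitter` 0.06, `regularity` 0;
#'   beechwood — `meanRadiusPx` 25.5, `radiusSdLog` 0.28, `aspectSdLog`
#'   0.13, `aspectSevFactor` 2.5, `ampMax` 0.85, `harmonics` 2:6,
#'   `shrinkMax` 0.30, `vesselSepPx` 6, `fibres` TRUE, `fibreMeanRadiusPx`
#'   5.2, `fibreRadiusSdLog` 0.22, `fibreKeepProb` 0.6, `regularity` 0.
#'   `regularity` in \[0, 1\] pulls shapes toward perfect circles (used by
#'   [calibrateToTarget()] for high circularity targets).
#' @return a [SectionSpec-class].
#' @seealso [generateSection()], [calibrateToTarget()]
#' @export
sectionSpec <- function(speciesMode = c("spruce", "beechwood"), nCells = 300L,
                        seed = 1L, pixelSizeUm = 0.8,
                        exposuresMs = seq(100, 3000, by = 100),
                        severity = 0, sizeScale = 1, wallGain = 0.0117,
                        lumenGainFrac = 0.04, noiseSd = 5,
                        illuminationAmplitude = 0.2, edgeSoftnessPx = 0.7,
                        imageSizePx = NA, shape = list()) {
  speciesMode <- match.arg(speciesMode)
  defaults <- if (speciesMode == "spruce") {
    list(meanLumenPx = 25.4, sizeSdLog = 0.29, fillMin = 0.80, fillMax = 0.95,
         wallPx = 5, cornerRadiusFrac = 0.30, ampMax = 0.45, harmonics = 2:6,
         shrinkMax = 0.30, jitterPx = 1.5, thetaJitter = 0.06, regularity = 0)
  } else {
    list(meanRadiusPx = 25.5, radiusSdLog = 0.28, aspectSdLog = 0.13,
         aspectSevFactor = 2.5, ampMax = 0.85, harmonics = 2:6,
         shrinkMax = 0.30, vesselSepPx = 6, fibres = TRUE,
         fibreMeanRadiusPx = 5.2, fibreRadiusSdLog = 0.22,
         fibreKeepProb = 0.6, regularity = 0)
  }
  unknown <- setdiff(names(shape), names(defaults))
  assertThat(length(unknown) == 0L, "unknown shape parameter(s): %s",
             paste(unknown, collapse = ", "))
  defaults[names(shape)] <- shape
  new("SectionSpec", speciesMode = speciesMode, nCells = as.integer(nCells),
      imageSizePx = if (length(imageSizePx) == 1L && is.na(imageSizePx))
        NA_integer_ else as.integer(imageSizePx),
      pixelSizeUm = pixelSizeUm, exposuresMs = as.numeric(exposuresMs),
      severity = severity, sizeScale = sizeScale, wallGain = wallGain,
      lumenGainFrac = lumenGainFrac, noiseSd = noiseSd,
      illuminationAmplitude = illuminationAmplitude,
      edgeSoftnessPx = edgeSoftnessPx, shape = defaults,
      seed = as.integer(seed))
}

# ---- lumen boundary model -------------------------------------------------
# Every lumen is star-shaped about its centre: r(phi) =
# base(phi - theta) * (1 + sum_k amp_k * cos(k * phi + ph_k)), with base
# either an ellipse or a rounded rectangle. The polar form makes exact
# point-in-lumen tests and supersampled rasterization cheap.

# radius of an ellipse with semi-axes a >= b along direction u (radians from
# its own major axis)
ellipseRadius <- function(a, b, u) {
  a * b / sqrt((b * cos(u))^2 + (a * sin(u))^2)
}

# radius of an axis-aligned rounded rectangle with half-sizes hw, hh and
# corner radius rho along direction u
roundedRectRadius <- function(hw, hh, rho, u) {
  cc <- abs(cos(u)); ss <- abs(sin(u))
  A <- hw - rho; B <- hh - rho
  t1 <- hw / pmax(cc, 1e-12)          # exit through the vertical flat
  t2 <- hh / pmax(ss, 1e-12)          # exit through the horizontal flat
  v1 <- t1 * ss <= B + 1e-12
  v2 <- t2 * cc <= A + 1e-12
  m <- A * cc + B * ss
  disc <- pmax(m^2 - (A^2 + B^2 - rho^2), 0)
  tc <- m + sqrt(disc)                # exit through the corner arc
  r <- ifelse(v1, t1, ifelse(v2, t2, tc))
  r
}

# full radius function of one lumen (row of the layout table) at angles phi
lumenRadius <- function(L, phi) {
  u <- phi - L$theta
  base <- if (L$kind == "ellipse") ellipseRadius(L$a, L$b, u)
          else roundedRectRadius(L$hw, L$hh, L$rho, u)
  mod <- 1 + L$amp2 * cos(2 * phi + L$ph2) + L$amp3 * cos(3 * phi + L$ph3) +
    L$amp4 * cos(4 * phi + L$ph4) + L$amp5 * cos(5 * phi + L$ph5) +
    L$amp6 * cos(6 * phi + L$ph6)
  base * pmax(mod, 0.05)
}

# draw per-lumen harmonic deformation: total amplitude grows with severity
drawHarmonics <- function(n, severity, ampMax, reg) {
  tot <- severity * ampMax * (1 - reg) * (0.6 + 0.8 * stats::runif(n))
  w <- matrix(stats::runif(5L * n), n, 5L)
  w <- w / pmax(rowSums(w), 1e-12) * tot
  ph <- matrix(stats::runif(5L * n, 0, 2 * pi), n, 5L)
  list(amp = w, ph = ph)
}

emptyHarm <- function(n) list(amp = matrix(0, n, 5L),
                              ph = matrix(0, n, 5L))

harmCols <- function(h) {
  out <- cbind(h$amp, h$ph)
  colnames(out) <- c(paste0("amp", 2:6), paste0("ph", 2:6))
  as.data.frame(out)
}

# ---- layout ---------------------------------------------------------------
# Deterministic given the spec seed. All random draws are made independently
# of severity/sizeScale (which act as smooth deterministic transforms), so
# calibration searches move along smooth monotone response curves.

layoutSpruce <- function(spec) {
  sh <- spec@shape
  n <- spec@nCells
  reg <- sh$regularity
  shrink <- 1 - sh$shrinkMax * spec@severity
  ncol. <- ceiling(sqrt(n))
  nrow. <- ceiling(n / ncol.)
  sdl <- sh$sizeSdLog * (1 - reg)

  W <- spec@sizeScale * sh$meanLumenPx *
    exp(stats::rnorm(ncol., 0, sdl) - sdl^2 / 2) + sh$wallPx
  H <- spec@sizeScale * sh$meanLumenPx *
    exp(stats::rnorm(nrow., 0, sdl) - sdl^2 / 2) + sh$wallPx
  margin <- sh$wallPx + 3
  xc <- margin + cumsum(W) - W / 2
  yc <- margin + cumsum(H) - H / 2
  width <- ceiling(2 * margin + sum(W))
  height <- ceiling(2 * margin + sum(H))

  ij <- cbind(rep(seq_len(nrow.), each = ncol.),
              rep(seq_len(ncol.), times = nrow.))[seq_len(n), , drop = FALSE]
  fill <- matrix(stats::runif(2L * n, sh$fillMin, sh$fillMax), n, 2L)
  jit <- matrix(stats::runif(2L * n, -sh$jitterPx, sh$jitterPx), n, 2L)
  theta <- stats::rnorm(n, 0, sh$thetaJitter * (1 - reg))
  harm <- drawHarmonics(n, spec@severity, sh$ampMax, reg)

  availW <- (W[ij[, 2L]] - sh$wallPx) / 2
  availH <- (H[ij[, 1L]] - sh$wallPx) / 2
  inflate <- 1 + rowSums(harm$amp)
  hw <- shrink * availW * fill[, 1L] / inflate
  hh <- shrink * availH * fill[, 2L] / inflate
  cf <- sh$cornerRadiusFrac + reg * (1 - sh$cornerRadiusFrac)
  rho <- cf * pmin(hw, hh)
  slackX <- pmax(availW - hw * inflate, 0)
  slackY <- pmax(availH - hh * inflate, 0)

  lum <- data.frame(
    id = seq_len(n), type = "tracheid", kind = "rrect",
    cx = xc[ij[, 2L]] + pmin(1, slackX / sh$jitterPx) * jit[, 1L],
    cy = yc[ij[, 1L]] + pmin(1, slackY / sh$jitterPx) * jit[, 2L],
    hw = hw, hh = hh, rho = rho, a = NA_real_, b = NA_real_, theta = theta)
  lum <- cbind(lum, harmCols(harm))
  lum$rmax <- sqrt(lum$hw^2 + lum$hh^2) * inflate
  list(lumens = lum, width = width, height = height)
}

layoutBeechwood <- function(spec) {
  sh <- spec@shape
  n <- spec@nCells
  reg <- sh$regularity
  shrink <- 1 - sh$shrinkMax * spec@severity

  r0 <- spec@sizeScale * sh$meanRadiusPx *
    exp(stats::rnorm(n, 0, sh$radiusSdLog * (1 - reg)) -
        (sh$radiusSdLog * (1 - reg))^2 / 2)
  la <- stats::rnorm(n, 0, sh$aspectSdLog) * (1 - reg) *
    (1 + sh$aspectSevFactor * spec@severity)
  q <- exp(abs(la))                       # aspect >= 1
  theta <- stats::runif(n, 0, pi)
  harm <- drawHarmonics(n, spec@severity, sh$ampMax, reg)
  a <- shrink * r0 * sqrt(q)
  b <- shrink * r0 / sqrt(q)
  rmax <- a * (1 + rowSums(harm$amp))

  side <- if (!anyNA(spec@imageSizePx)) NULL else
    ceiling(sqrt(n * mean(pi * rmax^2) * 3.6))
  width <- if (is.null(side)) spec@imageSizePx[1L] else side
  height <- if (is.null(side)) spec@imageSizePx[min(2L, length(spec@imageSizePx))] else side

  # dart throwing: vessels accepted when separated from all accepted ones;
  # largest first so the big vessels always find room
  ord <- order(rmax, decreasing = TRUE)
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L
  attempts <- 0L
  maxAttempts <- 2000L * n
  while (placed < n && attempts < maxAttempts) {
    attempts <- attempts + 1L
    i <- ord[placed + 1L]
    m <- rmax[i] + sh$vesselSepPx / 2 + 2
    if (width - 2 * m <= 1 || height - 2 * m <= 1) break
    px <- stats::runif(1L, m, width - m)
    py <- stats::runif(1L, m, height - m)
    if (placed > 0L) {
      j <- ord[seq_len(placed)]
      mind <- (rmax[i] + rmax[j] + sh$vesselSepPx)^2
      if (any((px - cx[j])^2 + (py - cy[j])^2 < mind)) next
    }
    cx[i] <- px; cy[i] <- py
    placed <- placed + 1L
  }
  assertThat(placed == n,
             "cannot place %d vessels in a %d x %d px image (placed %d)",
             n, width, height, placed)

  lum <- data.frame(
    id = seq_len(n), type = "vessel", kind = "ellipse",
    cx = cx, cy = cy, hw = NA_real_, hh = NA_real_, rho = NA_real_,
    a = a, b = b, theta = theta)
  lum <- cbind(lum, harmCols(harm))
  lum$rmax <- rmax

  if (isTRUE(sh$fibres)) {
    rf0 <- sh$fibreMeanRadiusPx * spec@sizeScale
    pitch <- 2 * rf0 * exp(2 * sh$fibreRadiusSdLog) + 3.5
    gx <- seq(pitch, width - pitch, by = pitch)
    gy <- seq(pitch, height - pitch, by = pitch)
    g <- expand.grid(x = gx, y = gy)
    nf <- nrow(g)
    keep <- stats::runif(nf) < sh$fibreKeepProb
    fr <- shrink * rf0 * exp(stats::rnorm(nf, 0, sh$fibreRadiusSdLog))
    fq <- exp(abs(stats::rnorm(nf, 0, 0.1)))
    fth <- stats::runif(nf, 0, pi)
    fharm <- drawHarmonics(nf, spec@severity, sh$ampMax * 0.5, reg)
    jx <- stats::runif(nf, -1.5, 1.5); jy <- stats::runif(nf, -1.5, 1.5)
    finfl <- 1 + rowSums(fharm$amp)
    frmax <- fr * sqrt(fq) * finfl
    # keep fibres clear of every vessel
    for (i in seq_len(n)) {
      d2 <- (g$x - cx[i])^2 + (g$y - cy[i])^2
      keep <- keep & d2 > (rmax[i] + frmax + 3)^2
    }
    if (any(keep)) {
      fib <- data.frame(
        id = n + seq_len(sum(keep)), type = "fibre", kind = "ellipse",
        cx = (g$x + jx)[keep], cy = (g$y + jy)[keep],
        hw = NA_real_, hh = NA_real_, rho = NA_real_,
        a = (fr * sqrt(fq))[keep], b = (fr / sqrt(fq))[keep],
        theta = fth[keep])
      fh <- lapply(fharm, function(m) m[keep, , drop = FALSE])
      fib <- cbind(fib, harmCols(fh))
      fib$rmax <- frmax[keep]
      lum <- rbind(lum, fib)
    }
  }
  list(lumens = lum, width = width, height = height)
}

layoutSection <- function(spec) {
  lay <- withSeed(spec@seed, {
    if (spec@speciesMode == "spruce") layoutSpruce(spec)
    else layoutBeechwood(spec)
  })
  if (!anyNA(spec@imageSizePx)) {
    w <- spec@imageSizePx[1L]
    h <- spec@imageSizePx[min(2L, length(spec@imageSizePx))]
    assertThat(lay$width <= w && lay$height <= h,
               "layout needs %d x %d px but imageSizePx is %d x %d; cannot place %d cells",
               lay$width, lay$height, w, h, spec@nCells)
    lay$width <- w; lay$height <- h
  }
  lay
}

# ---- ground truth ---------------------------------------------------------

kTruthPolyPoints <- 512L

lumenPolygon <- function(L, nPts = kTruthPolyPoints) {
  phi <- seq(0, 2 * pi, length.out = nPts + 1L)[-(nPts + 1L)]
  r <- lumenRadius(L, phi)
  cbind(x = L$cx + r * cos(phi), y = L$cy + r * sin(phi))
}

polygonPerimeter <- function(p) {
  sum(sqrt(diff(c(p[, 1L], p[1L, 1L]))^2 + diff(c(p[, 2L], p[1L, 2L]))^2))
}

# supersampled area of one lumen (px^2): fraction of ss x ss subpixel centres
# inside the exact boundary, over the lumen's bounding box
supersampledAreaPx <- function(L, ss = 8L) {
  xr <- c(L$cx - L$rmax - 1, L$cx + L$rmax + 1)
  yr <- c(L$cy - L$rmax - 1, L$cy + L$rmax + 1)
  xs <- seq(xr[1L], xr[2L], by = 1 / ss)
  ys <- seq(yr[1L], yr[2L], by = 1 / ss)
  dx <- rep(xs - L$cx, times = length(ys))
  dy <- rep(ys - L$cy, each = length(xs))
  d2 <- dx^2 + dy^2
  cand <- d2 <= (L$rmax + 0.5)^2
  phi <- atan2(dy[cand], dx[cand])
  inside <- d2[cand] <= lumenRadius(L, phi)^2
  sum(inside) / ss^2
}

# 1x coverage field of all lumens (0 = wall, 1 = lumen interior), with the
# linear edge ramp of width spec@edgeSoftnessPx
coverageField <- function(lay, spec) {
  cov <- matrix(0, lay$height, lay$width)
  edge <- max(spec@edgeSoftnessPx, 1e-6)
  for (i in seq_len(nrow(lay$lumens))) {
    L <- lay$lumens[i, ]
    r1 <- max(1L, floor(L$cy - L$rmax - 2)); r2 <- min(lay$height, ceiling(L$cy + L$rmax + 2))
    c1 <- max(1L, floor(L$cx - L$rmax - 2)); c2 <- min(lay$width, ceiling(L$cx + L$rmax + 2))
    if (r2 < r1 || c2 < c1) next
    dy <- (r1:r2) - L$cy
    dx <- (c1:c2) - L$cx
    DX <- matrix(dx, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
    DY <- matrix(dy, r2 - r1 + 1L, c2 - c1 + 1L)
    dist <- sqrt(DX^2 + DY^2)
    phi <- atan2(DY, DX)
    signed <- dist - matrix(lumenRadius(L, as.vector(phi)), nrow(dist))
    cl <- pmin(1, pmax(0, 0.5 - signed / edge))
    blk <- cov[r1:r2, c1:c2]
    cov[r1:r2, c1:c2] <- pmax(blk, cl)
  }
  cov
}

sectionTruth <- function(lay, spec, cov, supersample = 8L) {
  ps <- spec@pixelSizeUm
  n <- nrow(lay$lumens)
  polys <- vector("list", n)
  areaPx <- numeric(n); perimPx <- numeric(n)
  for (i in seq_len(n)) {
    L <- lay$lumens[i, ]
    polys[[i]] <- lumenPolygon(L)
    perimPx[i] <- polygonPerimeter(polys[[i]])
    areaPx[i] <- supersampledAreaPx(L, ss = supersample)
  }
  circ <- pmin(1, 4 * pi * areaPx / perimPx^2)
  wall <- cov < 0.5
  mcw <- mean(cov[wall])
  eff <- spec@wallGain * (1 - 0.55 * spec@severity)
  gw <- pmin(255, eff * spec@exposuresMs)
  gl <- pmin(255, spec@lumenGainFrac * eff * spec@exposuresMs)
  new("SectionTruth",
      lumens = data.frame(id = lay$lumens$id, type = lay$lumens$type,
                          cx = lay$lumens$cx, cy = lay$lumens$cy,
                          true_area_um2 = areaPx * ps^2,
                          true_perimeter_um = perimPx * ps,
                          true_circularity = circ,
                          area_px_1x = areaPx),
      polygons = polys, wallMask = wall,
      wallCurve = data.frame(exposure_ms = spec@exposuresMs,
                             true_mean_grey = gw * (1 - mcw) + gl * mcw),
      spec = spec)
}

# smooth multiplicative illumination field, normalised to mean 1; its spatial
# period is a substantial fraction of the image so CLAHE (block ~127 px) can
# compensate it
illuminationField <- function(width, height, amplitude) {
  if (amplitude <= 0) return(matrix(1, height, width))
  f1 <- stats::runif(2L, 0.4, 1.1); f2 <- stats::runif(2L, 0.4, 1.1)
  p <- stats::runif(2L, 0, 2 * pi)
  X <- matrix(seq_len(width) / width, height, width, byrow = TRUE)
  Y <- matrix(seq_len(height) / height, height, width)
  F <- cos(2 * pi * (f1[1L] * X + f1[2L] * Y) + p[1L]) *
       cos(2 * pi * (f2[1L] * X - f2[2L] * Y) + p[2L])
  I <- 1 + amplitude * F
  I / mean(I)
}

#' Generate a synthetic wood-section exposure stack with ground truth
#'
#' Lays out non-overlapping lumens (species geometry per the spec), applies
#' the severity-dependent shrinkage and boundary deformation, computes
#' per-lumen ground truth on the pre-noise, pre-illumination geometry (area
#' by supersampled rasterization, perimeter by polygon arc length), and
#' renders every exposure frame: wall grey `min(255, gain_eff * e)`, lumens
#' nearly dark, multiplied by the smooth illumination field, plus Gaussian
#' sensor noise, rounded and clipped to 8 bits. Fully reproducible from the
#' spec seed.
#'
#' @param spec a [SectionSpec-class].
#' @param supersample supersampling factor for ground-truth areas
#'   (default 8).
#' @return list with elements `stack` (an [ExposureStack-class]) and
#'   `truth` (a [SectionTruth-class]).
#' @export
generateSection <- function(spec, supersample = 8L) {
  lay <- layoutSection(spec)
  cov <- coverageField(lay, spec)
  truth <- sectionTruth(lay, spec, cov, supersample = supersample)
  eff <- spec@wallGain * (1 - 0.55 * spec@severity)
  stack <- withSeed(spec@seed + 1L, {
    illum <- illuminationField(lay$width, lay$height,
                               spec@illuminationAmplitude)
    frames <- lapply(spec@exposuresMs, function(e) {
      gw <- min(255, eff * e)
      gl <- min(255, spec@lumenGainFrac * eff * e)
      field <- (gw * (1 - cov) + gl * cov) * illum
      if (spec@noiseSd > 0)
        field <- field + stats::rnorm(length(field), 0, spec@noiseSd)
      GreyImage(clamp8(roundHalfUp(field)), spec@pixelSizeUm)
    })
    ExposureStack(frames, spec@exposuresMs)
  })
  list(stack = stack, truth = truth)
}

#' Write the per-lumen ground truth as CSV
#'
#' @param truth a [SectionTruth-class].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth@lumens, path, row.names = FALSE)
  invisible(path)
}

# ---- spec (de)serialization ----------------------------------------------

specToList <- function(spec) {
  list(species_mode = spec@speciesMode, n_cells = spec@nCells,
       image_size_px = if (anyNA(spec@imageSizePx)) NULL else spec@imageSizePx,
       pixel_size_um = spec@pixelSizeUm, exposures_ms = spec@exposuresMs,
       severity = spec@severity, size_scale = spec@sizeScale,
       wall_gain = spec@wallGain, lumen_gain_frac = spec@lumenGainFrac,
       noise_sd = spec@noiseSd,
       illumination_amplitude = spec@illuminationAmplitude,
       edge_softness_px = spec@edgeSoftnessPx, shape = spec@shape,
       seed = spec@seed)
}

specFromList <- function(x) {
  sectionSpec(speciesMode = x$species_mode, nCells = x$n_cells,
              seed = x$seed, pixelSizeUm = x$pixel_size_um,
              exposuresMs = x$exposures_ms, severity = x$severity,
              sizeScale = x$size_scale, wallGain = x$wall_gain,
              lumenGainFrac = x$lumen_gain_frac, noiseSd = x$noise_sd,
              illuminationAmplitude = x$illumination_amplitude,
              edgeSoftnessPx = x$edge_softness_px,
              imageSizePx = if (is.null(x$image_size_px)) NA else x$image_size_px,
              shape = if (is.null(x$shape)) list() else x$shape)
}

#' Read/write a SectionSpec as a YAML config
#'
#' A written spec regenerates its section exactly
#' (`generateSection(readSectionSpec(f))`).
#'
#' @param spec a [SectionSpec-class].
#' @param path YAML file path.
#' @return `writeSectionSpec`: `path` invisibly; `readSectionSpec`: a
#'   [SectionSpec-class].
#' @export
writeSectionSpec <- function(spec, path) {
  yaml::write_yaml(specToList(spec), path)
  invisible(path)
}

#' @rdname writeSectionSpec
#' @export
readSectionSpec <- function(path) {
  specFromList(yaml::read_yaml(path))
}
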