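# polygon shoelace area (px^2) — fast geometry-only truth used during
# calibration search; the emitted ground truth still uses the supersampled
# rasterization, with which it agrees to well under 0.5 %
shoelaceArea <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# geometry-only mean circularity / mean area (um^2) of a spec's primary
# lumens (tracheids or vessels; fibres excluded)
geometrySummary <- function(spec, nPts = 256L) {
  sh <- spec@shape
  if (spec@speciesMode == "beechwood") sh$fibres <- FALSE
  spec@shape <- sh
  lay <- layoutSection(spec)
  n <- nrow(lay$lumens)
  a <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    poly <- lumenPolygon(lay$lumens[i, ], nPts = nPts)
    a[i] <- shoelaceArea(poly)
    p[i] <- polygonPerimeter(poly)
  }
  circ <- pmin(1, 4 * pi * a / p^2)
  list(meanAreaUm2 = mean(a) * spec@pixelSizeUm^2,
       meanCirc = mean(circ))
}

specAtDial <- function(base, dial, sizeScale) {
  base@severity <- max(0, dial)
  base@shape$regularity <- max(0, -dial)
  base@sizeScale <- sizeScale
  base
}

#' Calibrate a synthetic section to target ground-truth statistics
#'
#' Searches the generator's deformation dial and size scale so that the
#' GROUND-TRUTH mean lumen area, mean circularity (over tracheids/vessels)
#' and true mean wall grey at a reference exposure match the requested
#' targets — typically a published condition summary used as recovery
#' fixture. The dial spans regularized shapes (toward perfect circles) at
#' one end and full severity deformation at the other; mean circularity is
#' monotone along it, so a bisection suffices. Mean area then follows from
#' an exact quadratic rescaling of lumen dimensions, and the wall gain from
#' the closed-form relation between gain, lumen coverage and the target
#' grey. Targets are matched within 2 percent for `nCells >= 300`
#' (circularity targets outside the geometrically achievable range of the
#' species raise an error; a target within 0.02 of the range edge is
#' clamped to it).
#'
#' @param speciesMode `"spruce"` or `"beechwood"`.
#' @param targetMeanAreaUm2 target mean lumen area (um^2), > 0.
#' @param targetMeanCircularity target mean circularity in (0, 1\].
#' @param targetWallGreyAt2000ms target true mean wall grey (8-bit levels)
#'   at the reference exposure.
#' @param nCells lumen count of the fixture.
#' @param seed RNG seed of the fixture.
#' @param referenceExposureMs exposure at which the wall-grey target is
#'   anchored (default 2000 ms).
#' @param ... further arguments passed to [sectionSpec()] (e.g. `noiseSd`,
#'   `exposuresMs`).
#' @return a calibrated [SectionSpec-class].
#' @seealso [generateSection()]
#' @export
calibrateToTarget <- function(speciesMode, targetMeanAreaUm2,
                              targetMeanCircularity, targetWallGreyAt2000ms,
                              nCells = 300L, seed = 1L,
                              referenceExposureMs = 2000, ...) {
  assertThat(targetMeanAreaUm2 > 0, "area target must be positive")
  assertThat(targetMeanCircularity > 0 && targetMeanCircularity <= 1,
             "circularity target must lie in (0, 1]")
  assertThat(targetWallGreyAt2000ms > 0, "wall-grey target must be positive")
  base <- sectionSpec(speciesMode = speciesMode, nCells = nCells,
                      seed = seed, ...)

  cHigh <- geometrySummary(specAtDial(base, -1, 1))$meanCirc
  cLow <- geometrySummary(specAtDial(base, 1, 1))$meanCirc
  assertThat(targetMeanCircularity <= cHigh + 0.02 &&
             targetMeanCircularity >= cLow - 0.02,
             "circularity target %.3f infeasible for %s geometry (achievable range [%.3f, %.3f])",
             targetMeanCircularity, speciesMode, cLow, cHigh)

  lo <- -1; hi <- 1
  if (targetMeanCircularity >= cHigh) { dial <- -1 }
  else if (targetMeanCircularity <= cLow) { dial <- 1 }
  else {
    for (iter in 1:22) {
      dial <- (lo + hi) / 2
      cMid <- geometrySummary(specAtDial(base, dial, 1))$meanCirc
      if (abs(cMid - targetMeanCircularity) < 0.002) break
      if (cMid > targetMeanCircularity) lo <- dial else hi <- dial
    }
  }

  # lumen linear dimensions scale exactly with sizeScale, so one step lands
  # on the area target; a second step absorbs residual layout effects
  scale <- 1
  for (iter in 1:3) {
    g <- geometrySummary(specAtDial(base, dial, scale))
    ratio <- targetMeanAreaUm2 / g$meanAreaUm2
    if (abs(ratio - 1) < 0.005) break
    scale <- scale * sqrt(ratio)
  }

  spec <- specAtDial(base, dial, scale)
  assertThat(referenceExposureMs %in% spec@exposuresMs,
             "reference exposure %g ms must be part of the exposure series",
             referenceExposureMs)

  # wall gain from the exact relation target = gw*(1-mcw) + gl*mcw at the
  # reference exposure, with mcw the mean lumen coverage over wall pixels
  lay <- layoutSection(spec)
  cov <- coverageField(lay, spec)
  wall <- cov < 0.5
  mcw <- mean(cov[wall])
  denom <- (1 - mcw) + spec@lumenGainFrac * mcw
  gwPerMs <- targetWallGreyAt2000ms / (referenceExposureMs * denom)
  spec@wallGain <- gwPerMs / (1 - 0.55 * spec@severity)
  assertThat(gwPerMs * max(spec@exposuresMs) * (1 + spec@illuminationAmplitude)
             < 256 * 1.6,
             "wall-grey target %.1f saturates the 8-bit range at the longest exposure",
             targetWallGreyAt2000ms)
  spec
}
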