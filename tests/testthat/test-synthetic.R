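smallSpec <- function(mode = "beechwood", n = 15L, seed = 5L, ...) {
  sectionSpec(mode, nCells = n, seed = seed,
              exposuresMs = c(500, 1000, 2000), ...)
}

test_that("a spec regenerates its section bit-identically", {
  spec <- smallSpec()
  s1 <- generateSection(spec)
  s2 <- generateSection(spec)
  expect_identical(lapply(frames(s1$stack), pixels),
                   lapply(frames(s2$stack), pixels))
  expect_identical(groundTruth(s1$truth), groundTruth(s2$truth))
  expect_identical(trueWallMask(s1$truth), trueWallMask(s2$truth))
  # and so does a spec written to and read back from YAML
  td <- withr::local_tempdir()
  writeSectionSpec(spec, file.path(td, "spec.yaml"))
  s3 <- generateSection(readSectionSpec(file.path(td, "spec.yaml")))
  expect_identical(lapply(frames(s3$stack), pixels),
                   lapply(frames(s1$stack), pixels))
})

test_that("generator randomness never leaks into the caller's RNG state", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateSection(smallSpec())); after <- runif(1)
  expect_identical(before, after)
})

test_that("severity monotonically shrinks and deforms the true geometry", {
  for (mode in c("spruce", "beechwood")) {
    circ <- numeric(3); area <- numeric(3)
    for (i in 1:3) {
      s <- c(0, 0.5, 1)[i]
      spec <- smallSpec(mode, n = 40L, seed = 8L, severity = s)
      tr <- groundTruth(generateSection(spec)$truth)
      tr <- tr[tr$type != "fibre", ]
      circ[i] <- mean(tr$true_circularity)
      area[i] <- mean(tr$true_area_um2)
    }
    expect_true(all(diff(circ) < 0))
    expect_true(all(diff(area) < 0))
  }
})

test_that("undeformed spruce tracheids are near-rectangular (mean circularity >= 0.75)", {
  spec <- smallSpec("spruce", n = 60L, seed = 3L, severity = 0)
  tr <- groundTruth(generateSection(spec)$truth)
  expect_gte(mean(tr$true_circularity), 0.75)
  expect_true(all(tr$true_circularity > 0 & tr$true_circularity <= 1))
})

test_that("8x and 16x supersampled truth areas agree within 0.5%", {
  spec <- smallSpec("beechwood", n = 10L, seed = 6L, severity = 0.6)
  a8 <- groundTruth(generateSection(spec, supersample = 8L)$truth)$true_area_um2
  a16 <- groundTruth(generateSection(spec, supersample = 16L)$truth)$true_area_um2
  expect_lt(max(abs(a8 - a16) / a16), 0.005)
})

test_that("ground-truth means are statistically reproducible across seeds", {
  means <- vapply(c(101L, 202L, 303L), function(sd) {
    tr <- groundTruth(generateSection(smallSpec("beechwood", n = 50L,
                                                seed = sd))$truth)
    mean(tr$true_circularity[tr$type == "vessel"])
  }, numeric(1))
  expect_lt(diff(range(means)), 0.05)
})

test_that("beechwood sections contain sub-threshold fibre lumens", {
  tr <- groundTruth(generateSection(smallSpec("beechwood", n = 12L))$truth)
  fib <- tr[tr$type == "fibre", ]
  expect_gt(nrow(fib), 20)
  expect_true(all(fib$area_px_1x < 500))
  expect_true(all(tr$area_px_1x[tr$type == "vessel"] > 500))
})

test_that("an image too small for the requested cells raises a placement error", {
  spec <- sectionSpec("beechwood", nCells = 100L, seed = 1L,
                      imageSizePx = c(220L, 220L),
                      exposuresMs = c(1000, 2000))
  expect_error(generateSection(spec), "cannot place|imageSizePx")
})

test_that("calibration matches ground truth to its targets within 2%", {
  spec <- calibrateToTarget("beechwood", targetMeanAreaUm2 = 1000,
                            targetMeanCircularity = 0.80,
                            targetWallGreyAt2000ms = 20,
                            nCells = 60L, seed = 19L)
  tr <- generateSection(spec)
  v <- groundTruth(tr$truth)
  v <- v[v$type == "vessel", ]
  expect_lt(abs(mean(v$true_area_um2) - 1000) / 1000, 0.02)
  expect_lt(abs(mean(v$true_circularity) - 0.80), 0.02)
  wg <- trueWallCurve(tr$truth)
  expect_lt(abs(wg$true_mean_grey[wg$exposure_ms == 2000] - 20) / 20, 0.02)
})

test_that("a perfect-circle target is feasible and an extreme one is rejected", {
  spec <- calibrateToTarget("beechwood", 1200, 1.0, 20, nCells = 40L,
                            seed = 23L)
  tr <- groundTruth(generateSection(spec)$truth)
  expect_gte(mean(tr$true_circularity[tr$type == "vessel"]), 0.98)
  expect_error(
    calibrateToTarget("beechwood", 1200, 0.05, 20, nCells = 40L, seed = 23L),
    "infeasible")
})
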