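test_that("particles are 8-connected and labelled in raster-scan order", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal touch
  expect_identical(max(labelParticles(m)), 1L)

  expect_identical(max(labelParticles(matrix(FALSE, 5, 5))), 0L)

  # first pixel in reading order (row-major) decides the label
  m2 <- matrix(FALSE, 6, 9)
  m2[5, 1:2] <- TRUE                         # later row
  m2[2, 6:7] <- TRUE                         # earlier row, later column
  lab <- labelParticles(m2)
  expect_identical(lab[2, 6], 1L)
  expect_identical(lab[5, 1], 2L)
})

test_that("interior holes are filled before measurement", {
  n <- 41
  d2 <- outer(1:n, 1:n, function(i, j) (i - 21)^2 + (j - 21)^2)
  annulus <- d2 <= 15^2 & d2 >= 7^2
  lab <- labelParticles(annulus)
  expect_identical(max(lab), 1L)
  expect_identical(sum(lab == 1L), sum(d2 <= 15^2))  # fill-then-count oracle
  # hole filling is a flag
  labOpen <- labelParticles(annulus, fillHoles = FALSE)
  expect_identical(sum(labOpen == 1L), sum(annulus))
})

test_that("the species size filter keeps exactly the at-or-above-bound particles", {
  drawBlob <- function(m, r0, c0, npx) {
    # a compact blob of exactly npx pixels (rows of width 10)
    rows <- ceiling(npx / 10)
    left <- npx
    for (i in seq_len(rows)) {
      w <- min(10L, left)
      m[r0 + i - 1L, c0:(c0 + w - 1L)] <- TRUE
      left <- left - w
    }
    m
  }
  m <- matrix(FALSE, 140, 80)
  m <- drawBlob(m, 10, 10, 19L)
  m <- drawBlob(m, 20, 10, 20L)
  m <- drawBlob(m, 30, 10, 499L)
  m <- drawBlob(m, 90, 10, 500L)
  ps <- measureLumens(m, particleFilter(1L, FALSE), 1)
  expect_identical(sort(ps$area_px), c(19L, 20L, 499L, 500L))

  spruce <- filterParticles(ps, particleFilter(20L, FALSE))
  expect_identical(sort(spruce$area_px), c(20L, 499L, 500L))
  beech <- filterParticles(ps, particleFilter(500L, FALSE))
  expect_identical(beech$area_px, 500L)

  # idempotence and the trivial filter
  expect_identical(filterParticles(spruce, particleFilter(20L, FALSE)), spruce)
  expect_identical(nrow(filterParticles(ps, particleFilter(1L, FALSE))), 4L)
})

test_that("edge-touching particles are excluded when requested", {
  m <- matrix(FALSE, 20, 20)
  m[1:4, 8:12] <- TRUE          # touches top edge
  m[10:14, 8:12] <- TRUE        # interior
  all2 <- measureLumens(m, particleFilter(1L, FALSE), 1)
  expect_identical(nrow(all2), 2L)
  expect_identical(sum(all2$touches_edge), 1L)
  kept <- measureLumens(m, particleFilter(1L, TRUE), 1)
  expect_identical(nrow(kept), 1L)
  expect_false(kept$touches_edge)
})

test_that("closed-form shapes measure to their analytic area, perimeter and circularity", {
  sq <- measureParticle(maskSquare(20L), 1)
  expect_equal(sq$area_um2, 400)
  expect_lt(abs(sq$perimeter_um - 80) / 80, 0.02)
  expect_lt(abs(sq$circularity - pi / 4), 0.03)

  disk <- measureParticle(maskDisk(50L), 1)
  expect_gte(disk$circularity, 0.95)
  expect_lte(disk$circularity, 1)
  expect_lt(abs(disk$perimeter_um - 2 * pi * 50) / (2 * pi * 50), 0.02)

  rect <- measureParticle(maskRect(100L, 25L), 1)
  expect_equal(rect$area_um2, 2500)
  expect_lt(abs(rect$circularity - 4 * pi * 2500 / 250^2), 0.03)

  # calibration scales area quadratically and perimeter linearly
  sq08 <- measureParticle(maskSquare(20L), 0.8)
  expect_equal(sq08$area_um2, 400 * 0.64)
  expect_equal(sq08$perimeter_um, sq$perimeter_um * 0.8)
  expect_equal(sq08$circularity, sq$circularity)
})

test_that("perimeter of convex digitized shapes is within 2% of the analytic contour", {
  set.seed(31)
  for (k in 1:8) {
    a <- runif(1, 12, 45)
    b <- runif(1, 10, a)
    th <- runif(1, 0, pi)
    rec <- measureParticle(maskEllipse(a, b, th), 1)
    expect_lt(abs(rec$perimeter_um - ellipsePerimeter(a, b)) /
                ellipsePerimeter(a, b), 0.02)
  }
})

test_that("circularity lies in (0,1] and is scale-invariant for similar shapes", {
  set.seed(32)
  for (scale in c(1, 2, 3)) {
    d <- measureParticle(maskDisk(12L * scale), 1)
    e <- measureParticle(maskEllipse(15 * scale, 9 * scale, 0.4), 1)
    expect_gt(d$circularity, 0)
    expect_lte(d$circularity, 1)
    if (scale > 1) {
      expect_lt(abs(e$circularity - eBase$circularity), 0.02)
      expect_gt(e$area_px, eBase$area_px)    # strictly increasing with scale
    }
    if (scale == 1) eBase <- e
  }
})

test_that("1x measurements agree with an 8x supersampled oracle within 3%", {
  # rasterize the same ellipse at 8x resolution; its measurement divided by
  # 8 (perimeter) and 64 (area) is the reference
  set.seed(33)
  for (k in 1:4) {
    a <- runif(1, 14, 30); b <- runif(1, 11, a); th <- runif(1, 0, pi)
    m1 <- maskEllipse(a, b, th)
    m8 <- maskEllipse(8 * a, 8 * b, th)
    r1 <- measureParticle(m1, 1)
    r8 <- measureParticle(m8, 1)
    expect_lt(abs(r1$area_px - r8$area_px / 64) / (r8$area_px / 64), 0.03)
    expect_lt(abs(r1$perimeter_um - r8$perimeter_um / 8) /
                (r8$perimeter_um / 8), 0.03)
  }
})

test_that("measureLumens counts drawn lumens and ignores specks below the bound", {
  set.seed(34)
  m <- matrix(FALSE, 600, 600)
  centers <- expand.grid(r = seq(50, 550, by = 100), c = seq(50, 550, by = 100))
  centers <- centers[sample(nrow(centers), 30), ]
  for (i in seq_len(30)) {
    a <- runif(1, 16, 22); b <- runif(1, 14, a)
    sub <- maskEllipse(a, b, runif(1, 0, pi), pad = 3L)
    rr <- centers$r[i] - nrow(sub) %/% 2; cc <- centers$c[i] - ncol(sub) %/% 2
    m[rr:(rr + nrow(sub) - 1), cc:(cc + ncol(sub) - 1)] <-
      m[rr:(rr + nrow(sub) - 1), cc:(cc + ncol(sub) - 1)] | sub
  }
  specks <- cbind(sample(5:595, 100, TRUE), sample(5:595, 100, TRUE))
  m2 <- m
  m2[specks] <- TRUE   # 1-px specks, some may land on lumens
  rec <- measureLumens(m2, particleFilter(500L, TRUE), 1)
  expect_identical(nrow(rec), 30L)
  expect_true(all(rec$area_px >= 500L))
  expect_identical(nrow(measureLumens(matrix(FALSE, 10, 10),
                                      particleFilter(1L), 1)), 0L)
  # deterministic and sorted by label
  rec2 <- measureLumens(m2, particleFilter(500L, TRUE), 1)
  expect_identical(rec, rec2)
  expect_identical(rec$label, sort(rec$label))
})
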