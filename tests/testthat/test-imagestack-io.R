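test_that("RGB conversion is the rounded channel mean with the stated conventions", {
  px <- function(r, g, b) {
    a <- array(c(r, g, b), dim = c(1, 1, 3))
    pixels(toGrey8(a, 0.8))[1, 1]
  }
  expect_identical(px(10, 20, 30), 20L)
  expect_identical(px(255, 255, 255), 255L)
  expect_identical(px(0, 0, 1), 0L)      # mean 1/3 rounds down
  expect_identical(px(0, 1, 1), 1L)      # mean 2/3 rounds up

  # permutation invariance and idempotence on grey triples
  set.seed(1)
  for (k in 1:20) {
    ch <- sample(0:255, 3, replace = TRUE)
    perms <- list(ch, ch[c(2, 3, 1)], ch[c(3, 1, 2)], ch[c(2, 1, 3)])
    vals <- vapply(perms, function(p) px(p[1], p[2], p[3]), integer(1))
    expect_true(all(vals == vals[1]))
    expect_identical(px(ch[1], ch[1], ch[1]), as.integer(ch[1]))
  }

  # luminance weighting is available and differs where channels differ
  a <- array(c(255, 0, 0), dim = c(1, 1, 3))
  expect_identical(pixels(toGrey8(a, 0.8, weights = "luminance"))[1, 1], 76L)
  expect_error(toGrey8(array(0, dim = c(2, 2, 2)), 0.8), "3 array")
})

test_that("GreyImage and ExposureStack enforce their invariants", {
  expect_error(GreyImage(matrix(-1, 2, 2), 0.8), "0, 255")
  expect_error(GreyImage(matrix(300, 2, 2), 0.8), "0, 255")
  expect_error(GreyImage(matrix(0L, 2, 2), -1), "positive")
  f <- GreyImage(matrix(0L, 4, 4), 0.8)
  expect_error(ExposureStack(list(f, f), c(200, 100, 300)), "frames")
  expect_error(new("ExposureStack", frames = list(f, f),
                   exposureMs = c(100, 100)), "strictly increasing")
  g <- GreyImage(matrix(0L, 4, 5), 0.8)
  expect_error(new("ExposureStack", frames = list(f, g),
                   exposureMs = c(100, 200)), "dimensions")
  # single-frame stack is valid
  s <- ExposureStack(list(f), 2000)
  expect_identical(nFrames(s), 1L)
})

test_that("stack TIFF round-trip is bit-exact including metadata", {
  set.seed(7)
  frames <- lapply(1:3, function(i)
    GreyImage(matrix(sample(0:255, 48, replace = TRUE), 8, 6), 0.8))
  st <- ExposureStack(frames, c(100, 700, 1900))
  path <- file.path(withr::local_tempdir(), "stack.tif")
  writeStack(st, path)
  rt <- readStack(path)
  expect_identical(exposureTimes(rt), exposureTimes(st))
  expect_identical(pixelSize(rt), 0.8)
  for (i in 1:3)
    expect_identical(pixels(frames(rt)[[i]]), pixels(frames(st)[[i]]))

  # full 30-frame exposure series: one page per frame, ascending order
  frames30 <- lapply(1:30, function(i)
    GreyImage(matrix((i * 7L) %% 256L, 4, 4), 0.8))
  ex <- seq(100, 3000, by = 100)
  st30 <- ExposureStack(frames30[sample(30)], ex[sample(30)])
  expect_identical(exposureTimes(st30), ex)  # constructor orders by exposure
  p30 <- file.path(withr::local_tempdir(), "s30.tif")
  writeStack(ExposureStack(frames30, ex), p30)
  rt30 <- readStack(p30)
  expect_identical(nFrames(rt30), 30L)
  expect_identical(exposureTimes(rt30)[c(1, 30)], c(100, 3000))
})

test_that("readStack reports contract violations with the offending path", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a_100ms.tif"); f2 <- file.path(td, "b_200ms.tif")
  writeStack(ExposureStack(list(GreyImage(matrix(1L, 6, 6), 0.8)), 100), f1)
  writeStack(ExposureStack(list(GreyImage(matrix(1L, 6, 7), 0.8)), 200), f2)
  expect_error(readStack(c(f1, f2), c(100, 200, 300), 0.8), "exposure")
  expect_error(readStack(c(f1, f2), c(100, 200), 0.8), "6x7")
  expect_error(readStack(file.path(td, "missing.tif"), 100, 0.8), "missing.tif")
  # per-file stacks assemble and order by exposure
  f3 <- file.path(td, "c_300ms.tif")
  writeStack(ExposureStack(list(GreyImage(matrix(2L, 6, 6), 0.8)), 300), f3)
  st <- readStack(c(f3, f1), c(300, 100), 0.8)
  expect_identical(exposureTimes(st), c(100, 300))
  expect_identical(pixels(frames(st)[[1]]), matrix(1L, 6, 6))
  expect_identical(exposureFromFilename(c("a_100ms.tif", "x.tif")),
                   c(100, NA))
})

test_that("RGB TIFF pages are converted on read", {
  td <- withr::local_tempdir()
  p <- file.path(td, "rgb.tif")
  a <- array(c(10, 255, 20, 255, 30, 255), dim = c(1, 2, 3)) / 255
  tiff::writeTIFF(a, p, bits.per.sample = 8L, compression = "none")
  st <- readStack(p, 500, 0.8)
  expect_identical(as.vector(pixels(frames(st)[[1]])), c(20L, 255L))
})

test_that("histograms count exactly and respect masks", {
  img <- GreyImage(matrix(c(0L, 0L, 255L, 255L), 2, 2), 1)
  h <- computeHistogram(img)
  expect_identical(histCounts(h)[c(1, 256)], c(2, 2))
  expect_identical(sum(histCounts(h)), 4)

  u <- GreyImage(matrix(7L, 10, 10), 1)
  hu <- computeHistogram(u)
  expect_identical(histCounts(hu)[8], 100)
  expect_identical(sum(histCounts(hu) != 0), 1L)

  set.seed(2)
  r <- GreyImage(matrix(sample(0:255, 300, replace = TRUE), 15, 20), 1)
  expect_identical(sum(histCounts(computeHistogram(r))), 300)  # conservation
  mask <- matrix(FALSE, 15, 20); mask[1:5, 1:4] <- TRUE
  expect_identical(sum(histCounts(computeHistogram(r, mask))), 20)
  expect_error(computeHistogram(r, matrix(FALSE, 15, 20)), "zero pixels")
  expect_error(computeHistogram(r, matrix(TRUE, 3, 3)), "dimensions")
})
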