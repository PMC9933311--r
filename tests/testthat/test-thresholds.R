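twoSpike <- function(l1 = 10, l2 = 200, n1 = 50, n2 = 50) {
  counts <- numeric(256)
  counts[l1 + 1] <- n1; counts[l2 + 1] <- n2
  counts
}

test_that("each threshold separates the modes of a two-spike histogram", {
  h <- newHist(twoSpike())
  for (m in c("huang", "li", "moments")) {
    lev <- thresholdLevel(autoThreshold(h, m))
    expect_gte(lev, 10)
    expect_lt(lev, 200)
    img <- GreyImage(matrix(c(10L, 10L, 200L, 200L), 2, 2), 1)
    expect_identical(applyThreshold(img, autoThreshold(h, m), "above"),
                     pixels(img) == 200L)
  }
})

test_that("degenerate single-level histograms return the level with a flag", {
  counts <- numeric(256); counts[38] <- 100
  h <- newHist(counts)
  for (m in c("huang", "li", "moments", "minimum")) {
    r <- autoThreshold(h, m)
    expect_identical(thresholdLevel(r), 37L)
    expect_true(r@degenerate)
  }
})

test_that("the toy 8-level histogram matches the exhaustive criterion scans", {
  counts <- numeric(256)
  counts[1:8] <- c(5, 40, 5, 0, 0, 5, 40, 5)
  h <- newHist(counts)
  # frozen values from the independent scan/solve oracles in helper-oracles.R
  expect_identical(thresholdLevel(thresholdHuang(h)), 2L)
  expect_identical(thresholdLevel(thresholdLi(h)), 2L)
  expect_identical(thresholdLevel(thresholdMoments(h)), 2L)
  expect_identical(oracleHuangScan(counts), 2L)
  expect_identical(oracleLiScan(counts), 2L)
  expect_identical(oracleMomentsSolve(counts), 2L)
})

test_that("thresholds equal their brute-force criterion minimisation on random mixtures", {
  set.seed(421)
  for (k in 1:60) {
    counts <- randomMixtureCounts()
    h <- newHist(counts)
    expect_identical(thresholdLevel(thresholdHuang(h)), as.integer(oracleHuangScan(counts)))
    expect_identical(thresholdLevel(thresholdLi(h)), as.integer(oracleLiScan(counts)))
    expect_identical(thresholdLevel(thresholdMoments(h)), as.integer(oracleMomentsSolve(counts)))
  }
})

test_that("threshold levels are invariant to uniform count scaling", {
  set.seed(77)
  for (k in 1:10) {
    counts <- randomMixtureCounts()
    for (m in c("huang", "li", "moments")) {
      expect_identical(thresholdLevel(autoThreshold(newHist(counts), m)),
                       thresholdLevel(autoThreshold(newHist(counts * 7), m)))
    }
  }
})

test_that("the minimum threshold finds the valley of a bimodal histogram", {
  g <- 0:255
  counts <- floor(0.5 + 200 * exp(-(g - 85)^2 / 50) +
                  200 * exp(-(g - 115)^2 / 50)) +
            as.numeric(g >= 70 & g <= 130)
  counts[101] <- 0   # the only empty bin, at level 100
  r <- thresholdMinimum(newHist(counts))
  expect_identical(thresholdLevel(r), 100L)
  expect_false(r@degenerate)
  # scaling invariance holds for the smoothing iteration too
  expect_identical(thresholdLevel(thresholdMinimum(newHist(counts * 3))), 100L)
})

test_that("the minimum threshold rejects unimodal histograms at the iteration cap", {
  g <- 0:255
  u <- floor(0.5 + 500 * exp(-(g - 120)^2 / 200))
  expect_error(thresholdMinimum(newHist(u)), "iteration cap of 10000")
  expect_error(thresholdMinimum(newHist(u), maxIter = 50L), "50")
})

test_that("histogram smoothing follows the stated boundary rule", {
  smoothOnce <- lignoquant:::smoothHistogram
  set.seed(3)
  h <- as.numeric(sample(0:50, 256, replace = TRUE))
  s <- smoothOnce(h)
  # independently coded expectation: 3-bin mean inside, 2-bin mean at edges
  expect_equal(s[1], (h[1] + h[2]) / 2)
  expect_equal(s[256], (h[255] + h[256]) / 2)
  i <- 2:255
  expect_equal(s[i], (h[i - 1] + h[i] + h[i + 1]) / 3)
  # away from the boundary the mean filter conserves total mass exactly:
  # with the first/last six bins empty, mass spreads one bin per pass and
  # the edge rule is not engaged for four passes
  h2 <- h; h2[c(1:6, 251:256)] <- 0
  s2 <- h2
  for (k in 1:4) {
    s2 <- smoothOnce(s2)
    expect_equal(sum(s2), sum(h2))
  }
})

test_that("the two threshold polarities partition the image exactly", {
  set.seed(9)
  img <- GreyImage(matrix(sample(0:255, 100, replace = TRUE), 10, 10), 1)
  r <- new("ThresholdResult", level = 100L, method = "huang",
           darkBackground = TRUE, degenerate = FALSE)
  above <- applyThreshold(img, r, "above")
  below <- applyThreshold(img, r, "at_or_below")
  expect_true(all(xor(above, below)))
  expect_identical(above, pixels(img) > 100L)
  # boundary: level 255 leaves no pixel above
  expect_false(any(applyThreshold(img, 255L, "above")))
  expect_true(all(applyThreshold(img, 255L, "at_or_below")))
})
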