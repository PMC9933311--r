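#' Pearson product-moment correlation
#'
#' Used to relate mean wall fluorescence to the morphological markers
#' (circularity, area) across pretreatment conditions. Thin validated
#' wrapper around [stats::cor()].
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
  assertThat(length(x) == length(y), "x and y must have equal length")
  assertThat(length(x) >= 3L, "at least 3 paired observations are required")
  assertThat(stats::var(x) > 0 && stats::var(y) > 0,
             "x and y must both have non-zero variance")
  stats::cor(x, y)
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' The multiplicity correction of the reference statistical workflow:
#' p-values are sorted ascending, the i-th smallest of k is adjusted to
#' `1 - (1 - p_(i))^(k - i + 1)`, adjusted values are made monotone
#' non-decreasing, capped at 1, and returned in input order. Adjusted
#' values always dominate the raw ones.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' holmSidakAdjust(c(0.01, 0.04))  # 1 - 0.99^2 = 0.0199, 0.04
#' @export
holmSidakAdjust <- function(p) {
  assertThat(is.numeric(p) && all(p >= 0 & p <= 1),
             "p-values must lie in [0, 1]")
  k <- length(p)
  if (k == 0L) return(numeric(0L))
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(k - seq_len(k) + 1L)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(k)
  out[o] <- adj
  out
}
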