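#' Pair a predicted and an experimental profile
#'
#' Validates that the two profiles cover the same residues (matched by
#' residue sequence number, at least 3) before correlation.
#'
#' @param predicted,experimental [fluct_profile()] objects with identical
#'   residue numbering.
#' @return A list of class `"profile_pair"` with `x` (predicted values),
#'   `y` (experimental values) and `n`.
#' @export
profile_pair <- function(predicted, experimental) {
  stopifnot(inherits(predicted, "fluct_profile"),
            inherits(experimental, "fluct_profile"))
  if (!identical(predicted$residue_numbers, experimental$residue_numbers))
    stop("profile_pair: residue numbering differs between profiles")
  n <- length(predicted$values)
  if (n < 3L) stop("profile_pair: at least 3 shared residues required")
  structure(list(x = predicted$values, y = experimental$values, n = n),
            class = "profile_pair")
}

as_xy <- function(x, y) {
  if (inherits(x, "profile_pair")) return(x)
  if (inherits(x, "fluct_profile")) return(profile_pair(x, y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("at least 3 values required")
  structure(list(x = x, y = y, n = length(x)), class = "profile_pair")
}

#' Pearson product-moment correlation of two profiles
#'
#' Standard product-moment coefficient over the shared residues: close to 1
#' when the two profiles are linearly (homothetically) related, -1 when
#' anticorrelated.
#'
#' @param x A `"profile_pair"`, a [fluct_profile()] (with `y` its partner),
#'   or a numeric vector.
#' @param y Second profile/vector when `x` is not a pair.
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' profile_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))   # 0.8
#' @export
profile_pearson <- function(x, y = NULL) {
  p <- as_xy(x, y)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
    stop("profile_pearson: correlation undefined for a constant profile")
  stats::cor(p$x, p$y, method = "pearson")
}

#' Spearman rank correlation of two profiles
#'
#' Residues are ranked by ascending fluctuation in each profile and the
#' product-moment correlation of the ranks is returned. Without ties this
#' equals the classical \eqn{1 - 6\sum d_i^2 / (n(n^2-1))} shortcut with
#' \eqn{d_i} the rank differences; ties are handled by average ranks.
#'
#' @inheritParams profile_pearson
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' profile_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
profile_spearman <- function(x, y = NULL) {
  p <- as_xy(x, y)
  if (length(unique(p$x)) == 1L || length(unique(p$y)) == 1L)
    stop("profile_spearman: correlation undefined for an all-tied profile")
  stats::cor(p$x, p$y, method = "spearman")
}

#' Skewness of a sample of correlation coefficients
#'
#' Moment-based skewness \eqn{g_1 = m_3 / m_2^{3/2}} with central moments
#' using the 1/n convention; `convention = "adjusted"` applies the usual
#' small-sample bias correction \eqn{\sqrt{n(n-1)}/(n-2)\, g_1}. Negative
#' values indicate a left tail: occasional poor predictions among mostly
#' good ones.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @param convention `"g1"` or `"adjusted"`.
#' @return The skewness coefficient.
#' @examples
#' coef_skewness(c(0, 0, 0, 1))   # 2/sqrt(3)
#' @export
coef_skewness <- function(values, convention = c("g1", "adjusted")) {
  convention <- match.arg(convention)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("coef_skewness: at least 3 values required")
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 == 0) stop("coef_skewness: undefined for a constant sample")
  g1 <- mean(d^3) / m2^1.5
  if (convention == "adjusted") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Histogram counts of correlation coefficients
#'
#' Fixed-width binning over \[-1, 1\] (default 0.1 bins): bins are
#' left-closed, right-open, except the last bin which is closed so that 1
#' is counted. Counts sum to the number of values.
#'
#' @param values Numeric vector with all values inside `range`.
#' @param bin_width Bin width.
#' @param range Two-element numeric range.
#' @return A data.frame with `lower`, `upper`, `count`.
#' @examples
#' h <- histogram_counts(c(0.05, 0.05, 0.15))
#' h[h$count > 0, ]
#' @export
histogram_counts <- function(values, bin_width = 0.1, range = c(-1, 1)) {
  values <- as.numeric(values)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (abs(breaks[length(breaks)] - range[2]) > 1e-12)
    stop("histogram_counts: range must be a whole number of bins")
  if (length(values) &&
      (any(values < range[1] - 1e-12) || any(values > range[2] + 1e-12)))
    stop("histogram_counts: values outside the histogram range")
  nb <- length(breaks) - 1L
  if (length(values) == 0L)
    counts <- integer(nb)
  else {
    # left-closed bins; clamp the right edge into the final bin
    bin <- pmin(pmax(floor((values - range[1]) / bin_width) + 1L, 1L), nb)
    counts <- tabulate(bin, nbins = nb)
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = counts)
}

#' Cumulative counting function of a sample
#'
#' Returns the right-continuous counting function N(x) = number of values
#' not exceeding x, as used for cumulative distribution plots of
#' correlation coefficients.
#'
#' @param values Numeric vector (may be empty).
#' @return A list of class `"cumulative_counts"` with `table` (a data.frame
#'   of the jump points `x` and counts) and `fun(x)`, a vectorized
#'   evaluator; `fun(x)` is 0 below the minimum and `length(values)` at and
#'   above the maximum.
#' @examples
#' cc <- cumulative_counts(c(0.2, 0.5))
#' cc$fun(0.3)
#' @export
cumulative_counts <- function(values) {
  values <- sort(as.numeric(values))
  n <- length(values)
  if (n == 0L) {
    tab <- data.frame(x = numeric(0), count = integer(0))
    f <- function(x) rep(0L, length(x))
  } else {
    ux <- unique(values)
    cnt <- cumsum(tabulate(match(values, ux)))
    tab <- data.frame(x = ux, count = cnt)
    f <- local({
      ux <- ux; cnt <- cnt
      function(x) {
        i <- findInterval(x, ux)
        out <- integer(length(x))
        out[i > 0] <- cnt[i[i > 0]]
        out
      }
    })
  }
  structure(list(table = tab, fun = f, n = n), class = "cumulative_counts")
}
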