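#' Linear-interpolation quantile
#'
#' The one quantile definition used throughout the package: linear
#' interpolation between closest order statistics (R type 7, the default
#' of `stats::quantile()` and of numpy's "linear" rule).
#'
#' @param x Numeric vector (NAs removed).
#' @param probs Probabilities in \[0, 1\].
#' @return Numeric vector of quantiles.
#' @export
linearQuantile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, na.rm = TRUE,
                         names = FALSE))
}

#' Significance marker for a p-value
#'
#' Star notation used in all reports: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05, empty string otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @examples
#' significanceMarker(c(0.0005, 0.005, 0.03, 0.2))
#' @export
significanceMarker <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' t-statistic implied by a Pearson correlation
#'
#' For a simple linear regression, the slope t-statistic equals
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom,
#' where `r` is the Pearson correlation of the same pair. This identity is
#' used both to compute correlation p-values and to cross-check printed
#' regression tables against printed correlation tables.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Number of complete pairs (so `df = n - 2`).
#' @return The implied t-statistic(s); `Inf` with sign of `r` when
#'   `|r| = 1`.
#' @examples
#' correlationTStat(0.561, 17)
#' @export
correlationTStat <- function(r, n) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE), all(n > 2))
  r <- pmin(1, pmax(-1, r))
  ifelse(abs(r) == 1, sign(r) * Inf, r * sqrt(n - 2) / sqrt(1 - r^2))
}

#' Two-sided p-value for a correlation via the t transform
#' @noRd
.corPValue <- function(r, n) {
  t <- correlationTStat(r, n)
  2 * stats::pt(-abs(t), df = n - 2)
}

# Deterministic substream seed: all randomness flows from one user seed;
# each module/participant draws from its own named substream so components
# can be regenerated independently. Kept below 2^31.
.substreamSeed <- function(seed, name, k = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 31 + k) %% 2147483647)
}

# Sample skewness / excess kurtosis (bias-corrected, e1071 type 2).
.skewness <- function(x) e1071::skewness(x, type = 2)
.kurtosis <- function(x) e1071::kurtosis(x, type = 2)
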