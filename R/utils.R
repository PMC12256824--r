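# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(e^a - e^b) for a >= b, stable; returns -Inf when the difference
# underflows (caller may warn and treat the mass as zero).
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b > a) return(NaN)
  if (b == a) return(-Inf)
  d <- b - a
  # log1p(-exp(d)) with d <= 0
  a + log1p(-exp(d))
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic 31-bit child seed from a parent seed and string labels, so
# any locus / cell type / trait can be regenerated in isolation.
#' @keywords internal
child_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(labs)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Weighted Pearson correlation
#'
#' Correlation of two vectors with observation weights,
#' \eqn{r_w = \sum w (x-\bar x_w)(y-\bar y_w) /
#'   \sqrt{\sum w (x-\bar x_w)^2 \sum w (y-\bar y_w)^2}}.
#' With equal weights this reduces to the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights; defaults to equal weights.
#' @return a single correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0))
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 2L || sum(w) == 0) return(NA_real_)
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  num <- sum(w * (x - mx) * (y - my))
  den <- sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}
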