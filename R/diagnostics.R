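#' Rhythmicity of a code-word stream
#'
#' Rhythmicity is `R = C / D` with `C` the number of distinct code-word
#' patterns and `D` the total number of patterns. A perfectly singleton
#' stream (one repeated pattern) attains the ideal lower bound `1 / D`;
#' values near 1 mean every segment produced a different word.
#'
#' @param words Non-empty character vector of code words.
#' @return A one-row tibble with `C`, `D`, `R`.
#' @examples
#' rhythmicity(c("AAAAAAA", "AAAAAAA", "EEEEEEE"))  # C = 2, D = 3
#' @export
rhythmicity <- function(words) {
  if (length(words) == 0) abort("`words` must be non-empty")
  C <- length(unique(words))
  D <- length(words)
  tibble(C = C, D = D, R = C / D)
}

#' Rescaled-range Hurst exponent
#'
#' Classic R/S estimate of long-range dependence: for dyadic window sizes
#' `w = 8, 16, ...` up to `n / 2` the series is cut into `floor(n / w)`
#' blocks; per block the range of the cumulative demeaned sum is divided by
#' the block SD, and the slope of `log(mean R/S)` on `log(w)` is the Hurst
#' exponent. Around 0.5 indicates a memoryless series, above 0.5
#' persistence, below 0.5 anti-persistence.
#'
#' @param values Numeric vector, length at least 64 and not constant.
#' @return The estimated Hurst exponent (single number).
#' @export
hurst_exponent <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 64) abort("at least 64 values are required")
  if (sd(x) == 0) abort("R/S is undefined for a constant series")
  sizes <- 8 * 2^(0:30)
  sizes <- sizes[sizes <= n / 2]
  rs <- vapply(sizes, function(w) {
    nb <- n %/% w
    vals <- vapply(seq_len(nb), function(b) {
      y <- x[((b - 1) * w + 1):(b * w)]
      s <- sd(y)
      if (s == 0) return(NA_real_)
      z <- cumsum(y - mean(y))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) abort("not enough usable window sizes for R/S")
  unname(coef(lm(log(rs[keep]) ~ log(sizes[keep])))[2])
}

#' Summary statistics of a value stream
#'
#' The per-(class, optimizer) descriptive battery applied to optimized
#' code-word value streams: moment statistics (same conventions as the
#' segment features), geometric and harmonic means (defined because
#' code-word values are strictly positive), the lag-1 Pearson correlation
#' of the stream (its serial correlation; near zero for uncorrelated
#' streams), and sample/approximate entropy with `m = 2`,
#' `r = 0.2 * SD` (`NA` for series shorter than 4 values).
#'
#' @param values Numeric vector, length at least 3, strictly positive.
#' @return A one-row tibble: `mean, variance, skewness, kurtosis,
#'   geometric_mean, harmonic_mean, pearson_cc, sample_entropy,
#'   approximate_entropy`.
#' @export
summarize_stream <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 3) abort("at least 3 values are required")
  if (any(x <= 0)) abort("geometric/harmonic means need strictly positive values")
  mo <- .fz_moments(x)
  n <- length(x)
  pcc <- if (mo$var == 0) 0 else stats::cor(x[-n], x[-1])
  tibble(mean = mo$mean, variance = mo$var, skewness = mo$skewness,
         kurtosis = mo$kurtosis,
         geometric_mean = exp(mean(log(x))),
         harmonic_mean = n / sum(1 / x),
         pearson_cc = pcc,
         sample_entropy = if (n >= 4) sample_entropy(x) else NA_real_,
         approximate_entropy = if (n >= 4) approx_entropy(x) else NA_real_)
}

#' First canonical correlation between two value matrices
#'
#' Measures shared structure between, e.g., the normal and CVD optimized
#' value matrices (subjects x positions). Rows are truncated to the common
#' count and columns to the common dimension; covariance blocks are
#' ridge-regularised (`eps = 1e-6` on the diagonal scale) so rank-deficient
#' inputs stay solvable, with a warning when regularisation is doing real
#' work.
#'
#' @param x,y Numeric matrices with at least 2 rows each.
#' @param eps Ridge factor applied as `eps * mean(diag)` to each
#'   within-set covariance block.
#' @return First canonical correlation in `[0, 1]`.
#' @export
cca_first <- function(x, y, eps = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- min(nrow(x), nrow(y))
  if (n < 2) abort("both matrices need at least 2 rows")
  d <- min(ncol(x), ncol(y))
  x <- scale(x[seq_len(n), seq_len(d), drop = FALSE], scale = FALSE)
  y <- scale(y[seq_len(n), seq_len(d), drop = FALSE], scale = FALSE)
  sxx <- crossprod(x) / (n - 1)
  syy <- crossprod(y) / (n - 1)
  sxy <- crossprod(x, y) / (n - 1)
  rxx <- eps * mean(diag(sxx)); ryy <- eps * mean(diag(syy))
  if (rxx == 0) rxx <- eps
  if (ryy == 0) ryy <- eps
  sxx <- sxx + diag(rxx, d)
  syy <- syy + diag(ryy, d)
  if (rcond(sxx) < 1e-10 || rcond(syy) < 1e-10) {
    warn("covariance blocks are near rank-deficient; ridge regularisation applied")
  }
  m <- solve(sxx, sxy) %*% solve(syy, t(sxy))
  ev <- eigen(m, only.values = TRUE)$values
  rho2 <- max(Re(ev))
  sqrt(min(max(rho2, 0), 1))
}
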