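#' Cut a PPG record into non-overlapping segments
#'
#' Splits the waveform into consecutive windows of `seg_seconds * fs`
#' samples (200 samples for two seconds at 100 Hz); a trailing remainder
#' shorter than one window is dropped. Concatenating the rows reproduces
#' the prefix of the record exactly.
#'
#' @param record A `ppg_record`, or a numeric vector with `fs` given.
#' @param seg_seconds Segment duration in seconds.
#' @param fs Sampling rate; taken from the record when omitted.
#' @return A numeric matrix, one row per segment.
#' @examples
#' rec <- generate_record(synth_spec(n_normal = 1, n_cvd = 1, n_segments = 3), "normal", 1)
#' dim(segment_record(rec))  # 3 x 200
#' @export
segment_record <- function(record, seg_seconds = 2, fs = NULL) {
  if (inherits(record, "ppg_record")) {
    x <- record$samples
    fs <- fs %||% record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) abort("`fs` is required when `record` is a bare vector")
  }
  .fz_check_number(seg_seconds, "seg_seconds", 0, strict = TRUE)
  w <- as.integer(round(seg_seconds * fs))
  if (length(x) < w) abort("record is shorter than one segment")
  k <- length(x) %/% w
  matrix(x[seq_len(k * w)], nrow = k, ncol = w, byrow = TRUE)
}

#' Approximate entropy (ApEn)
#'
#' Pincus-style approximate entropy with self-matches included and the
#' Chebyshev (maximum) distance: `ApEn = phi_m - phi_{m+1}` where
#' `phi_m` is the mean log fraction of templates within tolerance `r`.
#' By the convention used throughout this package, a constant (zero-SD)
#' series has ApEn 0.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(x)`.
#' @return A single number (dimensionless).
#' @export
approx_entropy <- function(x, m = 2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2) abort("series too short for approximate entropy")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  r <- r %||% (0.2 * s)
  d <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    nt <- n - mm + 1
    mx <- d[seq_len(nt), seq_len(nt), drop = FALSE]
    if (mm > 1) {
      for (k in seq_len(mm - 1)) {
        mx <- pmax(mx, d[k + seq_len(nt), k + seq_len(nt), drop = FALSE])
      }
    }
    mean(log(rowSums(mx <= r) / nt))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy (SampEn)
#'
#' Richman–Moorman sample entropy: self-matches excluded,
#' `SampEn = -log(A / B)` with `B` the count of template pairs matching at
#' length `m` and `A` at length `m + 1`, both over the first `n - m`
#' templates. Returns 0 for a constant series and `NA` when no template
#' pair matches at length `m + 1`.
#'
#' @inheritParams approx_entropy
#' @return A single number.
#' @export
sample_entropy <- function(x, m = 2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2) abort("series too short for sample entropy")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  r <- r %||% (0.2 * s)
  d <- abs(outer(x, x, "-"))
  count <- function(mm) {
    nt <- n - m  # both lengths use the first n - m templates
    mx <- d[seq_len(nt), seq_len(nt), drop = FALSE]
    if (mm > 1) {
      for (k in seq_len(mm - 1)) {
        mx <- pmax(mx, d[k + seq_len(nt), k + seq_len(nt), drop = FALSE])
      }
    }
    (sum(mx <= r) - nt) / 2  # unordered pairs, self-matches removed
  }
  b <- count(m)
  a <- count(m + 1)
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# Moment statistics shared by features and diagnostics: population moments
# m2..m4 about the mean; skewness = m3 / m2^1.5, kurtosis = m4 / m2^2
# (plain, non-excess). Degenerate (constant) input maps both to 0.
.fz_moments <- function(x) {
  mu <- mean(x)
  c2 <- x - mu
  m2 <- mean(c2^2)
  if (m2 == 0) {
    return(list(mean = mu, var = 0, std = 0, skewness = 0, kurtosis = 0))
  }
  n <- length(x)
  list(mean = mu, var = sum(c2^2) / (n - 1), std = sqrt(sum(c2^2) / (n - 1)),
       skewness = mean(c2^3) / m2^1.5, kurtosis = mean(c2^4) / m2^2)
}

#' Extract the eight segment features
#'
#' Computes, for one segment window, the eight parameters fed to the fuzzy
#' system: energy (raw sum of squares), variance and standard deviation
#' (unbiased, n-1), approximate entropy (`m = 2`, `r = 0.2 * SD`), mean,
#' skewness and plain (non-excess) kurtosis from population moments, and the
#' peak maximum. A constant window is degenerate: ApEn, skewness and
#' kurtosis are defined as 0.
#'
#' @param window Numeric vector of at least 4 samples.
#' @return A one-row tibble with columns `energy`, `variance`, `apen`,
#'   `mean`, `std`, `skewness`, `kurtosis`, `peak_max`.
#' @examples
#' extract_features(rep(c(1, -1), 100))
#' @export
extract_features <- function(window) {
  x <- as.numeric(window)
  if (length(x) < 4) abort("window must hold at least 4 samples")
  if (any(!is.finite(x))) abort("window contains non-finite samples")
  mo <- .fz_moments(x)
  tibble(energy = sum(x^2), variance = mo$var,
         apen = approx_entropy(x), mean = mo$mean, std = mo$std,
         skewness = mo$skewness, kurtosis = mo$kurtosis, peak_max = max(x))
}

# Vectorised feature extraction over a segment matrix (one row per window).
.fz_features_matrix <- function(w) {
  n <- ncol(w)
  mu <- rowMeans(w)
  cw <- w - mu
  s2 <- rowSums(cw^2)
  m2 <- s2 / n
  m3 <- rowMeans(cw^3)
  m4 <- rowMeans(cw^4)
  ok <- m2 > 0
  skew <- ifelse(ok, m3 / m2^1.5, 0)
  kurt <- ifelse(ok, m4 / m2^2, 0)
  apen <- vapply(seq_len(nrow(w)), function(i) approx_entropy(w[i, ]),
                 numeric(1))
  tibble(energy = rowSums(w^2), variance = s2 / (n - 1), apen = apen,
         mean = mu, std = sqrt(s2 / (n - 1)), skewness = skew,
         kurtosis = kurt, peak_max = apply(w, 1, max))
}

#' Per-segment feature table for a cohort
#'
#' Segments every record into `seg_seconds` windows and extracts the eight
#' features per segment.
#'
#' @param cohort Cohort tibble ([generate_cohort()] / [read_cohort()]).
#' @param seg_seconds Segment duration in seconds.
#' @return A tibble: `subject_id`, `label`, `segment` (1-based index) and
#'   the eight feature columns.
#' @export
ppg_features <- function(cohort, seg_seconds = 2) {
  out <- map(seq_len(nrow(cohort)), function(i) {
    w <- segment_record(cohort$samples[[i]], seg_seconds, fs = cohort$fs[i])
    f <- .fz_features_matrix(w)
    dplyr::bind_cols(tibble(subject_id = cohort$subject_id[i],
                            label = cohort$label[i],
                            segment = seq_len(nrow(w))), f)
  })
  bind_rows(out)
}

#' Detrend / rescale a PPG record
#'
#' A light preprocessing pass standing in for source separation, which is
#' not meaningful for a single channel: removes the least-squares linear
#' trend and optionally rescales the amplitude range. With both options
#' disabled the record is returned unchanged.
#'
#' @param record A `ppg_record`.
#' @param detrend Remove the best-fit linear trend?
#' @param rescale `NULL`, or `c(lo, hi)` to map the amplitude range onto.
#' @return A `ppg_record`.
#' @export
preprocess_record <- function(record, detrend = TRUE, rescale = NULL) {
  if (!inherits(record, "ppg_record")) abort("`record` must be a ppg_record")
  x <- record$samples
  if (isTRUE(detrend)) {
    t0 <- seq_along(x)
    beta <- cov(t0, x) / var(t0)
    x <- x - (mean(x) - beta * mean(t0)) - beta * t0 + mean(x)
  }
  if (!is.null(rescale)) {
    if (length(rescale) != 2 || rescale[1] >= rescale[2]) {
      abort("`rescale` must be c(lo, hi) with lo < hi")
    }
    rng <- range(x)
    if (diff(rng) > 0) {
      x <- rescale[1] + (x - rng[1]) / diff(rng) * diff(rescale)
    } else {
      x <- rep(mean(rescale), length(x))
    }
  }
  record$samples <- x
  record
}

#' Write / read a feature table as CSV
#'
#' @param features Feature tibble from [ppg_features()].
#' @param path CSV path.
#' @param comment Optional header comment line (written with a `#` prefix).
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the tibble.
#' @export
write_features <- function(features, path, comment = NULL) {
  if (!is.null(comment)) writeLines(paste0("# ", comment), path)
  readr::write_csv(features, path, append = !is.null(comment),
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(paste0("feature file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}
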