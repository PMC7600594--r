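#' The weighted risk alphabet
#'
#' The five output risk levels map to letters A (Normal) through E (Very
#' High). Each letter carries a five-bit one-hot binary string whose
#' positional value over 31 gives its weight, and a per-letter probability
#' = weight / 7 printed at six decimals. The printed six-decimal constants
#' are canonical throughout the package (so worked code-word values
#' reproduce digit-for-digit); the exact fractions differ from them by
#' under 1e-5 per seven-letter word.
#'
#' @return A tibble: `level`, `letter`, `bits`, `weight` (exact fraction),
#'   `probability` (printed six-decimal constant).
#' @examples
#' risk_alphabet()
#' @export
risk_alphabet <- function() {
  tibble(
    level = c("N", "L", "M", "H", "VH"),
    letter = c("A", "B", "C", "D", "E"),
    bits = c("00001", "00010", "00100", "01000", "10000"),
    weight = c(1, 2, 4, 8, 16) / 31,
    probability = c(0.004608, 0.009216, 0.018433, 0.036866, 0.073732)
  )
}

.fz_letter_prob <- c(A = 0.004608, B = 0.009216, C = 0.018433,
                     D = 0.036866, E = 0.073732)

#' Numeric value of code words
#'
#' Sums the per-letter probabilities (printed six-decimal constants) over
#' the letters of each word. Vectorised over a character vector.
#'
#' @param letters Character vector of words over the alphabet `A..E`
#'   (any length; seven letters for segment code words).
#' @return Numeric vector of values in `[0, 1]`.
#' @examples
#' codeword_value("EEDDCBE")  # 0.322577
#' @export
codeword_value <- function(letters) {
  if (!is.character(letters)) abort("`letters` must be character")
  vapply(strsplit(letters, ""), function(ch) {
    p <- .fz_letter_prob[ch]
    if (anyNA(p)) abort("code words may only use letters A-E")
    sum(p)
  }, numeric(1))
}

#' Encode seven subsystem output levels as a code word
#'
#' Maps the seven fuzzy output levels (in the fixed partner-feature order
#' variance, apen, mean, std, skewness, kurtosis, peak_max) to letters and
#' computes the word's value.
#'
#' @param levels Character vector of exactly 7 levels from
#'   `N, L, M, H, VH`.
#' @return A one-row tibble with `letters` and `value`.
#' @examples
#' encode_segment(c("VH", "VH", "H", "H", "M", "L", "VH"))  # EEDDCBE
#' @export
encode_segment <- function(levels) {
  if (length(levels) != 7) abort("exactly 7 output levels are required")
  idx <- match(levels, c("N", "L", "M", "H", "VH"))
  if (anyNA(idx)) abort("unknown output level; use N, L, M, H or VH")
  w <- paste0(c("A", "B", "C", "D", "E")[idx], collapse = "")
  tibble(letters = w, value = codeword_value(w))
}

#' Position-wise modal target code
#'
#' Condenses a window of code words into a single target word: at each of
#' the seven positions the modal letter is taken, with modal ties broken
#' toward the higher-risk letter. This is the package's documented
#' construction for a window's target pattern.
#'
#' @param words Character vector of equal-length code words.
#' @param window Optional index vector selecting a sub-window.
#' @return A one-row tibble with `letters` and `value`.
#' @examples
#' target_code(c("AAAAAAA", "EEEEEEE"))  # tie -> EEEEEEE
#' @export
target_code <- function(words, window = NULL) {
  if (!is.null(window)) words <- words[window]
  if (length(words) == 0) abort("the code-word window is empty")
  mat <- do.call(rbind, strsplit(words, ""))
  if (length(unique(nchar(words))) != 1) abort("words must share one length")
  modal <- apply(mat, 2, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    max(top)  # A < B < C < D < E, so max() is the higher-risk tie-break
  })
  w <- paste0(modal, collapse = "")
  tibble(letters = w, value = codeword_value(w))
}

#' Reduce a code-word stream to a fixed-length value vector
#'
#' Formalises the redundancy-removal step: duplicate letter strings are
#' dropped keeping first occurrences (so the surviving values stay in
#' original segment order); if more than `L` distinct words remain the `L`
#' earliest are kept, and if fewer the deduplicated values are cycled to
#' pad up to `L`. The result is the constant-dimension vector handed to the
#' optimizers and classifiers.
#'
#' @param words Character vector of code words in segment order, or a
#'   code-word tibble from [fuzzy_encode()] (column `letters`).
#' @param L Target length (default 375, half of the 750 segments per
#'   record).
#' @return Numeric vector of length `L` of code-word values.
#' @export
reduce_stream <- function(words, L = 375) {
  if (is.data.frame(words)) words <- words$letters
  if (length(words) == 0) abort("the code-word stream is empty")
  .fz_check_number(L, "L", 1)
  uniq <- words[!duplicated(words)]
  vals <- codeword_value(uniq)
  if (length(vals) >= L) {
    vals[seq_len(L)]
  } else {
    vals[((seq_len(L) - 1) %% length(vals)) + 1]
  }
}

#' Distribution views of a code-word value stream
#'
#' Computes the plot-ready arrays describing a (possibly optimized) value
#' stream: a histogram over equal-width bins, the right-continuous
#' empirical CDF evaluated at the sorted unique values, and normal
#' probability-plot points pairing order statistics with standard normal
#' quantiles at `(i - 0.5) / n`. Fuzzy-modeled streams show the
#' characteristic step-level CDF and heavy discretisation these views are
#' meant to expose.
#'
#' @param values Non-empty numeric vector.
#' @param bins Number of histogram bins.
#' @return An object of class `codeword_dist`: list with `breaks`, `counts`,
#'   `cdf` (tibble `value, prob`), `probplot` (tibble
#'   `theoretical, sample`), and `n`.
#' @export
codeword_distribution <- function(values, bins = 30) {
  if (length(values) == 0) abort("`values` must be non-empty")
  .fz_check_number(bins, "bins", 1)
  rng <- range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(values, breaks,
                                       rightmost.closed = TRUE), bins),
                     nbins = bins)
  xs <- sort(unique(values))
  cdf <- tibble(value = xs,
                prob = vapply(xs, function(v) mean(values <= v), numeric(1)))
  n <- length(values)
  probplot <- tibble(theoretical = qnorm((seq_len(n) - 0.5) / n),
                     sample = sort(values))
  structure(list(breaks = breaks, counts = counts, cdf = cdf,
                 probplot = probplot, n = n), class = "codeword_dist")
}

#' @export
print.codeword_dist <- function(x, ...) {
  cat(sprintf("<codeword_dist: %d values, %d bins, %d distinct>\n",
              x$n, length(x$counts), nrow(x$cdf)))
  invisible(x)
}

#' Plot a code-word value distribution
#'
#' @param object A `codeword_dist`.
#' @param type `"histogram"`, `"cdf"` or `"probability"` (normal
#'   probability plot).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.codeword_dist <- function(object,
                                   type = c("histogram", "cdf", "probability"),
                                   ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    mids <- (head(object$breaks, -1) + tail(object$breaks, -1)) / 2
    df <- tibble(value = mids, count = object$counts)
    ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$count)) +
      ggplot2::geom_col(width = diff(object$breaks)[1]) +
      ggplot2::labs(x = "code-word value", y = "count")
  } else if (type == "cdf") {
    ggplot2::ggplot(object$cdf, ggplot2::aes(.data$value, .data$prob)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(x = "code-word value", y = "F(x)")
  } else {
    ggplot2::ggplot(object$probplot,
                    ggplot2::aes(.data$theoretical, .data$sample)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(x = "normal quantile", y = "ordered value")
  }
}

#' Write / read code-word streams as CSV
#'
#' @param words Code-word tibble (`subject_id, label, segment, letters,
#'   value`).
#' @param path CSV path.
#' @param comment Optional `#`-prefixed header line.
#' @return `write_codewords()` returns `path` invisibly;
#'   `read_codewords()` the tibble.
#' @export
write_codewords <- function(words, path, comment = NULL) {
  if (!is.null(comment)) writeLines(paste0("# ", comment), path)
  readr::write_csv(words, path, append = !is.null(comment), col_names = TRUE)
  invisible(path)
}

#' @rdname write_codewords
#' @export
read_codewords <- function(path) {
  if (!file.exists(path)) abort(paste0("code-word file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, comment = "#",
                  col_types = readr::cols(letters = readr::col_character()))
}
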