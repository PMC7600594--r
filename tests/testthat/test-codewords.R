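test_that("code-word values reproduce the worked examples digit for digit", {
  expect_equal(codeword_value("EEDDCBE"), 0.322577)
  expect_equal(codeword_value("EEEEDEE"), 0.479258)
  expect_equal(floor(codeword_value("EEEEDEE") * 1e5) / 1e5, 0.47925)
  expect_equal(codeword_value("AAAAAAA"), 7 * 0.004608)
  expect_error(codeword_value("EEDDCBF"), "A-E")
})

test_that("alphabet constants derive from the five-bit positional weights", {
  ab <- risk_alphabet()
  expect_equal(ab$weight, c(1, 2, 4, 8, 16) / 31)
  expect_equal(sum(ab$weight), 1)
  expect_equal(round(ab$weight[ab$letter == "E"], 6), 0.516129)
  # printed probabilities are the 6-decimal truncations of weight / 7
  expect_equal(floor(ab$weight / 7 * 1e6) / 1e6, ab$probability)
  expect_equal(round((1 / 31) / 7, 6), 0.004608)
})

test_that("printed-constant and exact-fraction valuations stay within 1e-5", {
  ab <- risk_alphabet()
  exact <- stats::setNames(ab$weight / 7, ab$letter)
  set.seed(5)
  for (i in 1:50) {
    w <- paste(sample(c("A", "B", "C", "D", "E"), 7, replace = TRUE),
               collapse = "")
    v_exact <- sum(exact[strsplit(w, "")[[1]]])
    expect_lt(abs(codeword_value(w) - v_exact), 1e-5)
  }
})

test_that("value is invariant under letter permutation, the string is not", {
  set.seed(6)
  for (i in 1:20) {
    ltrs <- sample(c("A", "B", "C", "D", "E"), 7, replace = TRUE)
    w1 <- paste(ltrs, collapse = "")
    w2 <- paste(sample(ltrs), collapse = "")
    expect_equal(codeword_value(w1), codeword_value(w2))
  }
})

test_that("encode_segment maps output levels through the alphabet", {
  enc <- encode_segment(c("VH", "VH", "H", "H", "M", "L", "VH"))
  expect_equal(enc$letters, "EEDDCBE")
  expect_equal(enc$value, 0.322577)
  expect_error(encode_segment(c("VH", "VH")), "7")
  expect_error(encode_segment(rep("XX", 7)), "unknown")
})

test_that("target codes are position-wise modes with high-risk ties", {
  expect_equal(target_code(rep("BDEAEEE", 6))$letters, "BDEAEEE")
  expect_equal(target_code(c("AAAAAAA", "EEEEEEE"))$letters, "EEEEEEE")
  expect_error(target_code(character(0)), "empty")

  # the printed two-minute CVD window: 60 words; its position-wise mode
  # computed by explicit tally
  path <- system.file("extdata", "cvd_codeword_window.txt",
                      package = "fuzzppg")
  words <- scan(path, what = "", quiet = TRUE)
  expect_length(words, 60)
  mat <- do.call(rbind, strsplit(words, ""))
  tally <- apply(mat, 2, function(col) {
    tab <- table(col)
    max(names(tab)[tab == max(tab)])
  })
  expect_equal(target_code(words)$letters, paste(tally, collapse = ""))
  expect_equal(target_code(words)$letters, "BEEAEEE")
})

test_that("stream reduction dedups, truncates and pads as documented", {
  distinct <- vapply(1:375, function(i) {
    paste(c("A", "B", "C", "D", "E")[1 + (c(i, i %/% 5, i %/% 25, i %/% 125,
                                            i %% 3, i %% 7, i %% 11) %% 5)],
          collapse = "")
  }, character(1))
  distinct <- unique(distinct)
  doubled <- rep(distinct, each = 2)
  expect_equal(reduce_stream(doubled, L = length(distinct)),
               codeword_value(distinct))

  expect_equal(reduce_stream(rep("ABCDEAB", 40), L = 6),
               rep(codeword_value("ABCDEAB"), 6))

  ten <- c("AAAAAAA", "BBBBBBB", "CCCCCCC", "DDDDDDD", "EEEEEEE",
           "ABABABA", "BCBCBCB", "CDCDCDC", "DEDEDED", "EAEAEAE")
  expect_equal(reduce_stream(ten, L = 4), codeword_value(ten[1:4]))

  # idempotent on its own deduplicated output
  expect_equal(reduce_stream(ten, L = 10), reduce_stream(rep(ten, 3), L = 10))
})

test_that("distribution views satisfy their closed-form cases", {
  d <- codeword_distribution(rep(0.25, 10), bins = 5)
  expect_equal(sum(d$counts), 10)
  expect_equal(nrow(d$cdf), 1)
  expect_equal(d$cdf$prob, 1)

  d3 <- codeword_distribution(c(0.1, 0.2, 0.3), bins = 3)
  expect_equal(d3$counts, c(1, 1, 1))
  expect_equal(d3$cdf$prob[nrow(d3$cdf)], 1)  # CDF at the max is 1

  set.seed(2)
  v <- runif(200)
  dv <- codeword_distribution(v, bins = 12)
  expect_equal(sum(dv$counts), 200)
  expect_equal(nrow(dv$probplot), 200)
  expect_equal(dv$probplot$sample, sort(v))
})
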