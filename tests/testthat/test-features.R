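test_that("segmentation partitions the record and drops the remainder", {
  w <- segment_record(numeric(150000), 2, fs = 100)
  expect_equal(dim(w), c(750, 200))

  expect_equal(nrow(segment_record(seq_len(200), 2, fs = 100)), 1)
  w2 <- segment_record(seq_len(399), 2, fs = 100)
  expect_equal(dim(w2), c(1, 200))
  expect_equal(w2[1, ], 1:200)  # 199 trailing samples dropped

  x <- rnorm(1050)
  w3 <- segment_record(x, 2, fs = 100)
  expect_equal(as.numeric(t(w3)), x[1:1000])  # concatenation = prefix

  expect_error(segment_record(numeric(100), 2, fs = 100), "shorter")
})

test_that("feature values match hand computations on canonical windows", {
  z <- extract_features(numeric(200))
  expect_equal(z$energy, 0)
  expect_equal(z$variance, 0)
  expect_equal(z$mean, 0)
  expect_equal(z$peak_max, 0)
  expect_equal(z$apen, 0)       # degenerate window conventions
  expect_equal(z$skewness, 0)
  expect_equal(z$kurtosis, 0)

  alt <- extract_features(rep(c(1, -1), 100))
  expect_equal(alt$mean, 0)
  expect_equal(alt$variance, 200 / 199)
  expect_equal(alt$std, sqrt(200 / 199))
  expect_equal(alt$energy, 200)
  expect_equal(alt$peak_max, 1)

  expect_error(extract_features(c(1, 2, 3)), "4 samples")
})

test_that("features transform predictably under a constant shift", {
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(120)
    c0 <- 3.7
    a <- extract_features(x)
    b <- extract_features(x + c0)
    expect_equal(b$mean, a$mean + c0, tolerance = 1e-12)
    expect_equal(b$variance, a$variance, tolerance = 1e-12)
    expect_equal(b$std, a$std, tolerance = 1e-12)
    expect_equal(b$skewness, a$skewness, tolerance = 1e-9)
    expect_equal(b$kurtosis, a$kurtosis, tolerance = 1e-9)
    expect_equal(b$apen, a$apen, tolerance = 1e-9)
    expect_equal(b$energy, sum((x + c0)^2), tolerance = 1e-9)
    expect_equal(b$peak_max, a$peak_max + c0, tolerance = 1e-12)
    expect_gte(a$peak_max, a$mean)
  }
})

test_that("ApEn matches the brute-force oracle and known orderings", {
  for (s in 1:4) {
    set.seed(s)
    x <- rnorm(40)
    expect_equal(approx_entropy(x), apen_brute(x), tolerance = 1e-10)
  }
  set.seed(9)
  noise <- rnorm(200)
  sine <- sin(2 * pi * seq_len(200) / 40)
  expect_gt(approx_entropy(noise), apen_brute(sine))
})

test_that("entropies agree with an independent reference implementation", {
  skip_if_not_installed("pracma")
  for (s in 1:3) {
    set.seed(s)
    x <- rnorm(100)
    r <- 0.2 * sd(x)
    expect_equal(approx_entropy(x),
                 pracma::approx_entropy(x, edim = 2, r = r),
                 tolerance = 1e-10)
    expect_equal(sample_entropy(x),
                 pracma::sample_entropy(x, edim = 2, r = r),
                 tolerance = 1e-10)
  }
})

test_that("preprocessing detrends without touching anything else", {
  spec <- synth_spec(n_segments = 4)
  rec <- generate_record(spec, "normal", 1)

  ramp <- rec
  ramp$samples <- seq(0, 5, length.out = length(rec$samples))
  out <- preprocess_record(ramp, detrend = TRUE)
  t0 <- seq_along(out$samples)
  expect_lt(abs(stats::cov(t0, out$samples) / stats::var(t0)), 1e-12)

  expect_identical(preprocess_record(rec, detrend = FALSE)$samples,
                   rec$samples)

  # strong baseline wander: per-segment mean drift shrinks after detrending
  wspec <- synth_spec(n_segments = 10,
                      normal = list(baseline_amp = 2, baseline_freq = 0.02))
  wavy <- generate_record(wspec, "normal", 1)
  drift0 <- sd(rowMeans(segment_record(wavy)))
  drift1 <- sd(rowMeans(segment_record(preprocess_record(wavy))))
  expect_lt(drift1, drift0)

  sc <- preprocess_record(rec, detrend = FALSE, rescale = c(0, 1))
  expect_equal(range(sc$samples), c(0, 1))
})
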