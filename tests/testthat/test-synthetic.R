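test_that("record length is exactly n_segments x 2 x fs", {
  spec <- synth_spec(n_segments = 750)
  rec <- generate_record(spec, "normal", 1)
  expect_length(rec$samples, 150000)
  expect_true(all(is.finite(rec$samples)))

  for (ns in c(1, 3, 11)) {
    r <- generate_record(synth_spec(n_segments = ns), "cvd", 2)
    expect_length(r$samples, ns * 2 * 100)
  }
})

test_that("generation is deterministic in (seed, label, subject_index)", {
  spec <- synth_spec(n_segments = 5)
  a <- generate_record(spec, "cvd", 3)
  b <- generate_record(spec, "cvd", 3)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, generate_record(spec, "cvd", 4)$samples))
  expect_false(identical(a$samples,
                         generate_record(spec, "normal", 3)$samples))
})

test_that("spec validation names the offending field", {
  expect_error(synth_spec(fs = -1), "fs")
  expect_error(synth_spec(n_segments = 0), "n_segments")
  expect_error(synth_spec(normal = list(rr_jitter = -0.1)), "rr_jitter")
  expect_error(synth_spec(cvd = list(amp_scale = 0)), "amp_scale")
  expect_error(synth_spec(cvd = list(notch_delay = 1.5)), "notch_delay")
  expect_error(generate_record(synth_spec(), "healthy", 1), "label")
})

test_that("jitter-free records are strictly periodic", {
  quiet <- list(rr_jitter = 0, amp_jitter = 0, noise_sd = 0,
                baseline_amp = 0, heart_rate_bpm = 60)
  spec <- synth_spec(n_segments = 10, subject_cv = 0,
                     normal = quiet, cvd = quiet)
  rec <- generate_record(spec, "normal", 1)
  x <- rec$samples
  period <- 100  # one second at 60 bpm, 100 Hz
  lagged <- cor(x[seq_len(length(x) - period)], x[-seq_len(period)])
  expect_gt(lagged, 0.9999)

  # every 2-s segment yields the same feature vector
  ft <- ppg_features(tibble::tibble(subject_id = "s", label = "normal",
                                    fs = 100, samples = list(x)))
  for (col in c("energy", "variance", "apen", "mean", "std",
                "skewness", "kurtosis", "peak_max")) {
    expect_lt(diff(range(ft[[col]])), 1e-9)
  }
})

test_that("cohorts have the requested composition and unique ids", {
  co <- generate_cohort(synth_spec(n_normal = 14, n_cvd = 28,
                                   n_segments = 1))
  expect_equal(nrow(co), 42)
  expect_equal(sum(co$label == "cvd"), 28)
  expect_equal(anyDuplicated(co$subject_id), 0)

  co2 <- generate_cohort(synth_spec(n_normal = 1, n_cvd = 1,
                                    n_segments = 1))
  expect_equal(nrow(co2), 2)
  expect_setequal(co2$label, c("normal", "cvd"))

  expect_error(generate_cohort(synth_spec(n_normal = 0, n_segments = 1)),
               "n_normal")
})

test_that("cohort write/read round-trips through delimited text", {
  co <- generate_cohort(synth_spec(n_normal = 1, n_cvd = 1, n_segments = 2))
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(file.path(dir, "manifest.csv"))
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(back$label, co$label)
  for (i in 1:2) {
    expect_equal(back$samples[[i]], co$samples[[i]], tolerance = 1e-12)
  }
  expect_error(read_cohort(file.path(dir, "nope.csv")), "not found")
})

test_that("classes separate on mean segment energy across a 42-subject cohort", {
  co <- generate_cohort(synth_spec(n_segments = 25, seed = 11))
  ft <- ppg_features(co)
  per_subj <- tapply(ft$energy, ft$subject_id, mean)
  labs <- co$label[match(names(per_subj), co$subject_id)]
  p <- stats::wilcox.test(per_subj[labs == "cvd"],
                          per_subj[labs == "normal"])$p.value
  expect_lt(p, 0.01)
})
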