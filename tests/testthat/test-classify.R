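# Synthetic instance sets with a controlled class gap: 75-dimensional
# Gaussian frames whose class means differ by `gap` standard deviations.
make_instances <- function(n_per_class, gap, seed = 1, frame_length = 75) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(2 * n_per_class), function(i) {
      lab <- if (i <= n_per_class) "normal" else "cvd"
      mu <- if (lab == "cvd") gap else 0
      tibble::tibble(subject_id = sprintf("p%03d", i), label = lab,
                     values = list(rnorm(frame_length * 5, mean = mu)))
    })
    frame_instances(dplyr::bind_rows(rows), frame_length = frame_length)
  })
}

test_that("framing cuts 375-vectors into five labeled 75-frames", {
  vecs <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:42),
    label = rep(c("normal", "cvd"), c(14, 28)),
    values = lapply(1:42, function(i) seq_len(375) + i))
  inst <- frame_instances(vecs)
  expect_equal(nrow(inst), 210)
  expect_equal(sum(inst$subject_id == "p01"), 5)
  first <- as.numeric(inst[inst$subject_id == "p01" & inst$frame == 1,
                           paste0("V", 1:75)])
  expect_equal(first, 1:75 + 1)
  vcols <- paste0("V", 1:75)
  rebuilt <- as.numeric(t(as.matrix(
    inst[inst$subject_id == "p07", vcols])))
  expect_equal(rebuilt, vecs$values[[7]])

  bad <- vecs
  bad$values[[3]] <- 1:100
  expect_error(frame_instances(bad), "length")
})

test_that("metric formulas reproduce their closed-form evaluations", {
  perfect <- metric_formulas(100, 0, 0)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100, PI = 100, GDR = 100))

  m <- metric_formulas(90, 10, 10)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 90)
  expect_equal(m$accuracy, 90)
  expect_equal(m$PI, (90 - 10 - 10) / 90 * 100, tolerance = 1e-10)
  expect_equal(round(m$PI, 2), 77.78)
  expect_equal(m$GDR, 80)

  expect_equal(metric_formulas(10, 20, 20)$PI, -300)
  expect_equal(metric_formulas(50, 50, 0)$GDR, 0)  # half missed, no alarms

  # accuracy is identically the mean of the two printed ratios
  set.seed(10)
  pc <- sample(1:200, 50, TRUE)
  mc <- sample(0:100, 50, TRUE)
  fa <- sample(0:100, 50, TRUE)
  mm <- metric_formulas(pc, mc, fa)
  expect_equal(mm$accuracy, (mm$sensitivity + mm$specificity) / 2)

  zero <- metric_formulas(0, 0, 0)
  expect_true(all(is.na(unlist(zero))))
})

test_that("every classifier separates well-separated frames", {
  train <- make_instances(12, gap = 3, seed = 21)
  test <- make_instances(8, gap = 3, seed = 22)
  for (cl in c("LR", "FLDA", "KNN", "RBF", "MLP", "SVM_RBF")) {
    out <- fit_predict(cl, train, test, seed = 1)
    acc <- mean(out$pred == test$label)
    expect_gte(acc, 0.95)
    expect_true(all(out$score >= 0 & out$score <= 1))
  }
})

test_that("KNN returns the unanimous neighbor label and FLDA degrades to chance without signal", {
  base <- make_instances(6, gap = 0.5, seed = 3)
  train <- base[c(1:5, 31:55), ]
  train[1:5, paste0("V", 1:75)] <- as.list(rep(0.5, 75))
  train$label[1:5] <- "normal"
  probe <- train[1, ]
  out <- fit_predict("KNN", train, probe, seed = 1)
  expect_equal(out$pred, "normal")

  nosig <- make_instances(15, gap = 0, seed = 4)
  res <- fit_predict("FLDA", nosig, make_instances(15, gap = 0, seed = 5))
  acc <- mean(res$pred == make_instances(15, gap = 0, seed = 5)$label)
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)

  oneclass <- nosig[nosig$label == "cvd", ]
  expect_error(fit_predict("LR", oneclass, nosig), "both classes")
})

test_that("the Fisher discriminant agrees with the reference LDA", {
  skip_if_not_installed("MASS")
  train <- make_instances(15, gap = 1, seed = 51)
  test <- make_instances(10, gap = 1, seed = 52)
  ours <- fit_predict("FLDA", train, test, seed = 1)
  vcols <- paste0("V", 1:75)
  fit <- MASS::lda(as.matrix(train[, vcols]), grouping = train$label)
  ref <- as.character(predict(fit, as.matrix(test[, vcols]))$class)
  expect_gt(mean(ours$pred == ref), 0.95)
})

test_that("cross-validation partitions instances and tallies PC/MC/FA per class", {
  inst <- make_instances(10, gap = 3, seed = 30)
  rep <- cross_validate(inst, "FLDA", folds = 5, seed = 2)
  expect_s3_class(rep, "class_report")
  expect_equal(rep$class, c("normal", "cvd", "average"))
  n_norm <- sum(inst$label == "normal")
  # every instance is predicted exactly once out-of-fold
  expect_equal(rep$PC[1] + rep$MC[1], n_norm)
  expect_equal(rep$PC[2] + rep$MC[2], sum(inst$label == "cvd"))
  expect_equal(rep$MC[1], rep$FA[2])  # misses of one class alarm the other
  expect_equal(rep$MC[2], rep$FA[1])

  # strongly separated data: perfect metrics straight from the formulas
  expect_equal(rep$sensitivity[3], 100)
  expect_equal(rep$accuracy[3], 100)
  expect_equal(rep$GDR[3], 100)

  expect_error(cross_validate(inst[1:12, ], "FLDA", folds = 10),
               "at least")
})

test_that("grouped folds keep a patient's frames together", {
  inst <- make_instances(10, gap = 1, seed = 31)
  rep <- cross_validate(inst, "KNN", folds = 5, seed = 9,
                        group_by_patient = TRUE)
  expect_equal(rep$class, c("normal", "cvd", "average"))
  expect_true(all(rep$PC[1:2] + rep$MC[1:2] == 50))
})

test_that("MSE uses the configured target coding", {
  inst <- make_instances(10, gap = 2, seed = 33)
  r01 <- cross_validate(inst, "FLDA", folds = 5, seed = 1)
  rt <- cross_validate(inst, "FLDA", folds = 5, seed = 1,
                       target_values = c(normal = 0.10, cvd = 0.26))
  expect_false(isTRUE(all.equal(r01$MSE, rt$MSE)))
  expect_true(all(rt$MSE >= 0))
  # perfectly scored positives against target 1 give near-zero MSE only
  # in the 0/1 coding
  expect_lt(r01$MSE[2], rt$MSE[2] + 1)
})

test_that("report accessors expose classifier and averages", {
  inst <- make_instances(10, gap = 1.5, seed = 40)
  rep <- cross_validate(inst, "KNN", folds = 5, seed = 3)
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_equal(unique(td$classifier), "KNN")
  gl <- glance(rep)
  expect_equal(gl$class, "average")
  expect_s3_class(autoplot(rep), "ggplot")
})
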