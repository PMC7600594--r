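.fz_classifiers <- c("LR", "FLDA", "KNN", "RBF", "MLP", "SVM_RBF")

#' Frame per-patient value vectors into classifier instances
#'
#' Reconciles the length-375 optimized vectors with the 75-input
#' classifiers: each patient's vector is cut into 5 consecutive
#' non-overlapping frames of 75 values, each frame becoming one instance
#' labeled with the patient's class. Concatenating a patient's frames
#' reproduces the original vector.
#'
#' @param vectors A tibble with columns `subject_id`, `label` and a
#'   `values` list-column of equal-length numeric vectors (default length
#'   375).
#' @param frame_length Values per instance (default 75).
#' @return An `instance_set` tibble: `subject_id`, `label`, `frame`,
#'   and feature columns `V1..V<frame_length>`.
#' @export
frame_instances <- function(vectors, frame_length = 75) {
  need <- c("subject_id", "label", "values")
  if (!all(need %in% names(vectors))) {
    abort("`vectors` must have columns subject_id, label, values")
  }
  lens <- lengths(vectors$values)
  if (length(unique(lens)) != 1 || lens[1] %% frame_length != 0) {
    abort(paste0("all value vectors must share one length that is a ",
                 "multiple of frame_length = ", frame_length))
  }
  k <- lens[1] %/% frame_length
  rows <- map(seq_len(nrow(vectors)), function(i) {
    m <- matrix(vectors$values[[i]], nrow = k, ncol = frame_length,
                byrow = TRUE)
    colnames(m) <- paste0("V", seq_len(frame_length))
    dplyr::bind_cols(tibble(subject_id = vectors$subject_id[i],
                            label = vectors$label[i], frame = seq_len(k)),
                     as_tibble(m))
  })
  out <- bind_rows(rows)
  class(out) <- c("instance_set", class(out))
  out
}

.fz_xy <- function(instances) {
  vcols <- grep("^V[0-9]+$", names(instances), value = TRUE)
  list(x = as.matrix(instances[, vcols]),
       y = as.integer(instances$label == "cvd"))
}

# --- individual classifiers; each returns list(pred = 0/1, score in [0,1]).

.fz_fit_lr <- function(xtr, ytr, xte) {
  df <- as.data.frame(xtr); df$.y <- ytr
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  sc <- suppressWarnings(
    as.numeric(predict(fit, newdata = as.data.frame(xte), type = "response")))
  list(pred = as.integer(sc > 0.5), score = sc)
}

# Fisher linear discriminant: ridge-stabilised pooled within-class
# covariance, projection threshold at the midpoint of the projected class
# means, oriented so the positive class scores higher.
.fz_fit_flda <- function(xtr, ytr, xte) {
  m0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
  m1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  c0 <- cov(xtr[ytr == 0, , drop = FALSE])
  c1 <- cov(xtr[ytr == 1, , drop = FALSE])
  n0 <- sum(ytr == 0); n1 <- sum(ytr == 1)
  sw <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  sw <- sw + diag(1e-4 * mean(diag(sw)) + 1e-12, ncol(xtr))
  w <- solve(sw, m1 - m0)
  thr <- sum(w * (m0 + m1)) / 2
  proj <- as.numeric(xte %*% w) - thr
  s <- sd(as.numeric(xtr %*% w))
  if (!is.finite(s) || s == 0) s <- 1
  list(pred = as.integer(proj > 0), score = plogis(proj / s))
}

# K-nearest neighbours, K = 5, Euclidean, majority vote with ties toward
# the positive (cvd) class.
.fz_fit_knn <- function(xtr, ytr, xte, k = 5) {
  k <- min(k, nrow(xtr))
  d2 <- outer(rowSums(xte^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xte)), rowSums(xtr^2)) - 2 * xte %*% t(xtr)
  sc <- apply(d2, 1, function(dr) {
    mean(ytr[order(dr)[seq_len(k)]])
  })
  list(pred = as.integer(sc >= 0.5), score = sc)
}

# RBF network 75-30-1: hidden centers by k-means on the training set,
# shared width = mean inter-center distance, linear output layer by least
# squares, decision threshold 0.5.
.fz_fit_rbf <- function(xtr, ytr, xte, hidden = 30, seed = 1) {
  centers <- min(hidden, nrow(unique(as.data.frame(xtr))) - 1L)
  centers <- max(centers, 2L)
  km <- with_seed(as.integer(seed), {
    kmeans(xtr, centers = centers, iter.max = 50, nstart = 1)
  })
  ctr <- km$centers
  dcc <- as.matrix(stats::dist(ctr))
  sigma <- mean(dcc[upper.tri(dcc)])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  phi <- function(x) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(ctr))) +
      outer(rep(1, nrow(x)), rowSums(ctr^2)) - 2 * x %*% t(ctr)
    cbind(1, exp(-pmax(d2, 0) / (2 * sigma^2)))
  }
  wts <- qr.solve(phi(xtr), ytr)
  out <- as.numeric(phi(xte) %*% wts)
  list(pred = as.integer(out > 0.5), score = pmin(pmax(out, 0), 1))
}

# MLP 75-25-1, tanh hidden / logistic output, full-batch Rprop on the MSE,
# trained until the MSE target is reached or the epoch cap hits.
.fz_fit_mlp <- function(xtr, ytr, xte, hidden = 25, mse_target = 1e-4,
                       max_epochs = 2000, seed = 1) {
  nin <- ncol(xtr)
  mu <- colMeans(xtr); sg <- apply(xtr, 2, sd); sg[sg == 0] <- 1
  xs <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
  xe <- sweep(sweep(xte, 2, mu), 2, sg, "/")
  n <- nrow(xs)
  with_seed(as.integer(seed), {
    w1 <- matrix(runif(nin * hidden, -0.5, 0.5) / sqrt(nin), nin, hidden)
    b1 <- numeric(hidden)
    w2 <- runif(hidden, -0.5, 0.5) / sqrt(hidden)
    b2 <- 0
    d_w1 <- matrix(0.01, nin, hidden); d_b1 <- rep(0.01, hidden)
    d_w2 <- rep(0.01, hidden); d_b2 <- 0.01
    g_w1 <- matrix(0, nin, hidden); g_b1 <- numeric(hidden)
    g_w2 <- numeric(hidden); g_b2 <- 0
    rprop <- function(g, g_old, d) {
      s <- sign(g) * sign(g_old)
      d <- ifelse(s > 0, pmin(d * 1.2, 1), ifelse(s < 0, pmax(d * 0.5, 1e-8), d))
      list(step = -sign(g) * d, d = d, g = ifelse(s < 0, 0, g))
    }
    for (ep in seq_len(max_epochs)) {
      h <- tanh(sweep(xs %*% w1, 2, b1, "+"))
      o <- plogis(as.numeric(h %*% w2) + b2)
      err <- o - ytr
      mse <- mean(err^2)
      if (mse <= mse_target) break
      go <- 2 * err * o * (1 - o) / n
      gw2 <- as.numeric(crossprod(h, go))
      gb2 <- sum(go)
      gh <- outer(go, w2) * (1 - h^2)
      gw1 <- crossprod(xs, gh)
      gb1 <- colSums(gh)
      up <- rprop(gw1, g_w1, d_w1); w1 <- w1 + up$step; d_w1 <- up$d; g_w1 <- up$g
      up <- rprop(gb1, g_b1, d_b1); b1 <- b1 + up$step; d_b1 <- up$d; g_b1 <- up$g
      up <- rprop(gw2, g_w2, d_w2); w2 <- w2 + up$step; d_w2 <- up$d; g_w2 <- up$g
      up <- rprop(gb2, g_b2, d_b2); b2 <- b2 + up$step; d_b2 <- up$d; g_b2 <- up$g
    }
    h <- tanh(sweep(xe %*% w1, 2, b1, "+"))
    sc <- plogis(as.numeric(h %*% w2) + b2)
    list(pred = as.integer(sc > 0.5), score = sc)
  })
}

# SVM with RBF kernel; gamma picked from the 0.001..0.01 grid by inner
# 3-fold CV; a subsample guard caps the training set (and hence the
# support-vector count) at `max_sv`.
.fz_fit_svm <- function(xtr, ytr, xte, seed = 1, max_sv = 1800) {
  if (nrow(xtr) > max_sv) {
    keep <- with_seed(as.integer(seed), sample.int(nrow(xtr), max_sv))
    xtr <- xtr[keep, , drop = FALSE]; ytr <- ytr[keep]
  }
  gammas <- seq(0.001, 0.01, by = 0.001)
  folds <- with_seed(as.integer(seed), {
    f <- numeric(length(ytr))
    for (cl in 0:1) {
      idx <- sample(which(ytr == cl))
      f[idx] <- rep_len(1:3, length(idx))
    }
    f
  })
  acc <- vapply(gammas, function(g) {
    hits <- 0L
    for (fd in 1:3) {
      tr <- folds != fd
      if (length(unique(ytr[tr])) < 2) return(0)
      fit <- e1071::svm(xtr[tr, , drop = FALSE], factor(ytr[tr]),
                        kernel = "radial", gamma = g, scale = TRUE)
      hits <- hits + sum(predict(fit, xtr[!tr, , drop = FALSE]) == ytr[!tr])
    }
    hits / length(ytr)
  }, numeric(1))
  g <- gammas[which.max(acc)]
  fit <- e1071::svm(xtr, factor(ytr), kernel = "radial", gamma = g,
                    scale = TRUE)
  pr_all <- predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr_all, "decision.values")
  flip <- identical(colnames(dv)[1], "0/1")
  dv <- as.numeric(dv)
  if (flip) dv <- -dv
  pr <- as.integer(as.character(pr_all))
  list(pred = pr, score = plogis(dv))
}

#' Train one classifier and predict a test set
#'
#' The six-classifier bank: logistic regression (`LR`), Fisher linear
#' discriminant (`FLDA`), 5-nearest-neighbours (`KNN`, Euclidean, ties to
#' the positive class), an RBF network (`RBF`, k-means centers, 30 hidden
#' units, linear least-squares output), a 25-hidden-unit tanh/logistic
#' multilayer perceptron (`MLP`, trained to an MSE target of `1e-4` or
#' 2000 epochs), and an RBF-kernel SVM (`SVM_RBF`, gamma tuned on
#' `0.001..0.01` by inner 3-fold CV).
#'
#' @param classifier One of `"LR", "FLDA", "KNN", "RBF", "MLP", "SVM_RBF"`.
#' @param train,test `instance_set` tibbles ([frame_instances()]); the
#'   training set must contain both classes.
#' @param seed Seed for the stochastic fitters (k-means, MLP init, SVM
#'   tuning folds).
#' @return A tibble with one row per test instance: `pred` (label) and
#'   `score` (continuous output in `[0, 1]`, oriented toward `"cvd"`).
#' @export
fit_predict <- function(classifier, train, test, seed = 1) {
  classifier <- match.arg(classifier, .fz_classifiers)
  tr <- .fz_xy(train); te <- .fz_xy(test)
  if (length(unique(tr$y)) < 2) {
    abort("training data must contain both classes")
  }
  res <- switch(classifier,
                LR = .fz_fit_lr(tr$x, tr$y, te$x),
                FLDA = .fz_fit_flda(tr$x, tr$y, te$x),
                KNN = .fz_fit_knn(tr$x, tr$y, te$x),
                RBF = .fz_fit_rbf(tr$x, tr$y, te$x, seed = seed),
                MLP = .fz_fit_mlp(tr$x, tr$y, te$x, seed = seed),
                SVM_RBF = .fz_fit_svm(tr$x, tr$y, te$x, seed = seed))
  tibble(pred = ifelse(res$pred == 1, "cvd", "normal"),
         score = as.numeric(res$score))
}

#' The bespoke classification metric formulas
#'
#' Computes, from the perfect-classification (`PC`), missed-classification
#' (`MC`) and false-alarm (`FA`) counts, the evaluation battery used by
#' this pipeline — implemented exactly as printed in its source
#' literature, which differs from the textbook definitions:
#' sensitivity `= PC / (PC + FA) * 100`, specificity
#' `= PC / (PC + MC) * 100`, accuracy `= (sensitivity + specificity) / 2`,
#' performance index `PI = (PC - MC - FA) / PC * 100` (negative when the
#' errors outnumber the correct calls), and good detection rate
#' `GDR = (PC - MC) / (PC + FA) * 100`. Undefined ratios (zero
#' denominators) are reported as `NA`.
#'
#' @param PC,MC,FA Non-negative counts (vectorised).
#' @return A tibble: `sensitivity, specificity, accuracy, PI, GDR`
#'   (percentages).
#' @examples
#' metric_formulas(90, 10, 10)
#' @export
metric_formulas <- function(PC, MC, FA) {
  sens <- ifelse(PC + FA > 0, PC / (PC + FA) * 100, NA_real_)
  spec <- ifelse(PC + MC > 0, PC / (PC + MC) * 100, NA_real_)
  tibble(sensitivity = sens, specificity = spec,
         accuracy = (sens + spec) / 2,
         PI = ifelse(PC > 0, (PC - MC - FA) / PC * 100, NA_real_),
         GDR = ifelse(PC + FA > 0, (PC - MC) / (PC + FA) * 100, NA_real_))
}

# Stratified fold assignment (optionally grouped by patient).
.fz_folds <- function(instances, folds, seed, group_by_patient) {
  with_seed(as.integer(seed), {
    f <- integer(nrow(instances))
    if (group_by_patient) {
      pts <- dplyr::distinct(instances, .data$subject_id, .data$label)
      pf <- integer(nrow(pts))
      for (cl in .fz_labels) {
        idx <- sample(which(pts$label == cl))
        pf[idx] <- rep_len(seq_len(folds), length(idx))
      }
      f <- pf[match(instances$subject_id, pts$subject_id)]
    } else {
      for (cl in .fz_labels) {
        idx <- sample(which(instances$label == cl))
        f[idx] <- rep_len(seq_len(folds), length(idx))
      }
    }
    f
  })
}

#' Cross-validate a classifier on an instance set
#'
#' Stratified k-fold cross-validation with pooled out-of-fold predictions.
#' For each reported class, `PC` counts that class's instances predicted
#' correctly, `MC` those predicted as the other class, and `FA` the other
#' class's instances predicted as this one; the metric battery is then
#' computed by [metric_formulas()]. The mean squared error compares the
#' classifier's continuous outputs (0/1 predictions where no continuous
#' output exists) against per-class target values — by convention the
#' values of class-wise modal target code words; with `target_values =
#' NULL` the plain 0/1 class coding is used.
#'
#' By default frames of one patient may fall in different folds (the
#' per-segment counting convention of this pipeline); set
#' `group_by_patient = TRUE` for leakage-free patient-grouped folds.
#'
#' @param instances An `instance_set` ([frame_instances()]).
#' @param classifier Classifier name, see [fit_predict()].
#' @param folds Number of folds (default 10); each class needs at least
#'   `folds` instances.
#' @param seed Seed controlling fold assignment and the fitters.
#' @param target_values Named vector `c(normal = , cvd = )` of MSE targets,
#'   or `NULL` for 0/1 coding.
#' @param group_by_patient Keep each patient's frames in one fold?
#' @return A `class_report` tibble with rows `normal`, `cvd` and
#'   `average`: counts `PC, MC, FA`, the five metric columns and `MSE`.
#' @export
cross_validate <- function(instances, classifier, folds = 10, seed = 1,
                           target_values = NULL, group_by_patient = FALSE) {
  classifier <- match.arg(classifier, .fz_classifiers)
  counts <- table(factor(instances$label, .fz_labels))
  if (any(counts < folds)) {
    abort(paste0("each class needs at least ", folds, " instances"))
  }
  fold <- .fz_folds(instances, folds, seed, group_by_patient)
  pred <- character(nrow(instances))
  score <- numeric(nrow(instances))
  for (fd in seq_len(folds)) {
    te <- fold == fd
    if (!any(te)) next
    out <- fit_predict(classifier, instances[!te, ], instances[te, ],
                       seed = seed + fd)
    pred[te] <- out$pred
    score[te] <- out$score
  }
  truth <- instances$label
  per_class <- map(.fz_labels, function(cl) {
    pc <- sum(truth == cl & pred == cl)
    mc <- sum(truth == cl & pred != cl)
    fa <- sum(truth != cl & pred == cl)
    tv <- if (is.null(target_values)) as.numeric(cl == "cvd") else {
      unname(target_values[cl])
    }
    mse <- mean((score[truth == cl] - tv)^2)
    dplyr::bind_cols(tibble(class = cl, PC = pc, MC = mc, FA = fa),
                     metric_formulas(pc, mc, fa), tibble(MSE = mse))
  })
  rep <- bind_rows(per_class)
  avg <- dplyr::summarise(rep, class = "average",
                          across(c("PC", "MC", "FA"), sum),
                          across(c("sensitivity", "specificity", "accuracy",
                                   "PI", "GDR", "MSE"),
                                 ~ mean(.x, na.rm = TRUE)))
  out <- bind_rows(rep, avg)
  attr(out, "classifier") <- classifier
  attr(out, "folds") <- folds
  class(out) <- c("class_report", class(out))
  out
}

#' @describeIn cross_validate Tidy the per-class rows (drops the average).
#' @param x,object A `class_report`.
#' @param ... Ignored.
#' @export
tidy.class_report <- function(x, ...) {
  y <- as_tibble(x)[x$class != "average", ]
  y$classifier <- attr(x, "classifier")
  y
}

#' @describeIn cross_validate One-row summary (the averaged metrics).
#' @export
glance.class_report <- function(x, ...) {
  y <- as_tibble(x)[x$class == "average", ]
  y$classifier <- attr(x, "classifier")
  y
}

#' @describeIn cross_validate Bar chart of the metric battery by class.
#' @export
autoplot.class_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("class", "sensitivity", "specificity", "accuracy",
                          "PI", "GDR")],
    -"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent",
                  title = attr(object, "classifier"))
}
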