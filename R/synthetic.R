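#' Specification for a two-class synthetic PPG cohort
#'
#' Defines the study conditions for the synthetic photoplethysmography (PPG)
#' generator: cohort composition, sampling, and per-class waveform
#' parameters. The default cohort is 28 cardiovascular-disorder (CVD) and 14
#' normal subjects sampled at 100 Hz, each 750 two-second segments long
#' (150,000 samples), matching the benchmark framing this pipeline targets.
#'
#' Each class block holds the pulse model parameters:
#' \describe{
#'   \item{heart_rate_bpm}{mean pulse rate (beats per minute).}
#'   \item{rr_jitter}{coefficient of variation of inter-pulse intervals.}
#'   \item{amp_scale, amp_jitter}{mean pulse amplitude (arbitrary units) and
#'     its CV; amplitudes are log-normal so larger jitter also skews beats.}
#'   \item{pulse_skew}{relative widening of the falling edge of the systolic
#'     peak (0 = symmetric).}
#'   \item{notch_delay, notch_amp}{dicrotic-notch timing as a fraction of the
#'     mean pulse period, and its amplitude relative to the beat.}
#'   \item{noise_sd}{additive white Gaussian noise SD.}
#'   \item{baseline_amp, baseline_freq}{baseline-wander sinusoid amplitude and
#'     frequency (Hz).}
#'   \item{offset}{DC offset of the waveform.}
#' }
#'
#' The CVD class defaults use a faster, more irregular pulse (higher
#' `rr_jitter`, `amp_jitter`, `pulse_skew`) with larger amplitude, which
#' drives its segment features into higher linguistic risk bands than the
#' normal class.
#'
#' @param n_normal,n_cvd Number of subjects per class.
#' @param fs Sampling rate in Hz.
#' @param n_segments Number of two-second segments per record; the record
#'   length is exactly `n_segments * 2 * fs` samples.
#' @param seed Root RNG seed; subject `i` uses stream `seed + i`.
#' @param subject_cv Between-subject coefficient of variation: each
#'   subject's heart rate, amplitude scale, DC offset and interval jitter
#'   are drawn around the class values with this relative spread, so
#'   subjects within a class differ the way members of a clinical cohort
#'   do (0 disables it).
#' @param normal,cvd Named lists overriding individual class parameters.
#' @return An object of class `synth_spec`.
#' @examples
#' spec <- synth_spec(n_normal = 1, n_cvd = 1, n_segments = 5)
#' rec <- generate_record(spec, "cvd", 1)
#' length(rec$samples)  # 5 * 2 * 100
#' @export
synth_spec <- function(n_normal = 14, n_cvd = 28, fs = 100, n_segments = 750,
                       seed = 1, subject_cv = 0.07, normal = list(),
                       cvd = list()) {
  base_normal <- list(
    heart_rate_bpm = 70, rr_jitter = 0.03, amp_scale = 1.0, amp_jitter = 0.06,
    pulse_skew = 0.10, notch_delay = 0.35, notch_amp = 0.30, noise_sd = 0.03,
    baseline_amp = 0.10, baseline_freq = 0.25, offset = 1.0)
  base_cvd <- list(
    heart_rate_bpm = 85, rr_jitter = 0.10, amp_scale = 1.45, amp_jitter = 0.18,
    pulse_skew = 0.35, notch_delay = 0.28, notch_amp = 0.15, noise_sd = 0.06,
    baseline_amp = 0.15, baseline_freq = 0.30, offset = 1.15)
  spec <- structure(list(
    n_normal = n_normal, n_cvd = n_cvd, fs = fs, n_segments = n_segments,
    seed = seed, subject_cv = subject_cv,
    normal = utils::modifyList(base_normal, normal),
    cvd = utils::modifyList(base_cvd, cvd)), class = "synth_spec")
  validate_synth_spec(spec)
}

#' Validate a synthetic-cohort specification
#'
#' Checks every field of a [synth_spec()] and aborts with a message naming
#' the offending field.
#'
#' @param spec A `synth_spec`.
#' @return The spec, invisibly unchanged, if valid.
#' @export
validate_synth_spec <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort("`spec` must be a synth_spec")
  .fz_check_number(spec$fs, "fs", 0, strict = TRUE)
  .fz_check_number(spec$n_segments, "n_segments", 1)
  .fz_check_number(spec$n_normal, "n_normal", 0)
  .fz_check_number(spec$n_cvd, "n_cvd", 0)
  .fz_check_number(spec$seed, "seed")
  .fz_check_number(spec$subject_cv, "subject_cv", 0)
  for (cls in .fz_labels) {
    p <- spec[[cls]]
    for (f in c("rr_jitter", "amp_jitter", "noise_sd", "baseline_amp",
                "baseline_freq", "notch_amp", "pulse_skew")) {
      .fz_check_number(p[[f]], paste0(cls, "$", f), 0)
    }
    .fz_check_number(p$heart_rate_bpm, paste0(cls, "$heart_rate_bpm"), 0,
                     strict = TRUE)
    .fz_check_number(p$amp_scale, paste0(cls, "$amp_scale"), 0, strict = TRUE)
    .fz_check_number(p$offset, paste0(cls, "$offset"))
    if (p$notch_delay < 0 || p$notch_delay >= 1) {
      abort(paste0("`", cls, "$notch_delay` must be in [0, 1)"))
    }
  }
  spec
}

#' Generate one synthetic PPG record
#'
#' Synthesises a pulsatile waveform as a train of beats (an asymmetric
#' systolic Gaussian plus a delayed, smaller dicrotic Gaussian) on top of a
#' baseline-wander sinusoid, a DC offset and additive white noise.
#' Inter-beat intervals and beat amplitudes are jittered per the class block
#' of `spec`. The beat train is extended two mean periods beyond both record
#' edges so boundary segments carry full pulse tails.
#'
#' Generation is deterministic given `(spec$seed, label, subject_index)`:
#' the subject stream is `spec$seed + subject_index`.
#'
#' @param spec A [synth_spec()].
#' @param label `"normal"` or `"cvd"`.
#' @param subject_index Positive integer identifying the subject stream.
#' @return A `ppg_record`: list with `subject_id`, `label`, `fs`, `samples`
#'   (length `n_segments * 2 * fs`).
#' @export
generate_record <- function(spec, label, subject_index) {
  validate_synth_spec(spec)
  .fz_check_label(label)
  .fz_check_number(subject_index, "subject_index", 1)
  p <- spec[[label]]
  fs <- spec$fs
  dur <- spec$n_segments * 2
  n <- as.integer(round(dur * fs))
  tbar <- 60 / p$heart_rate_bpm

  samples <- with_seed(as.integer(spec$seed + subject_index), {
    # subject-level effects: who this subject is within their class
    cv <- spec$subject_cv
    zs <- pmax(1 + cv * rnorm(4), 0.3)
    tbar <- tbar / zs[1]
    amp_scale <- p$amp_scale * zs[2]
    offset <- p$offset * zs[3]
    rr_jitter <- p$rr_jitter * zs[4]
    m <- ceiling((dur + 4 * tbar) / (0.4 * tbar)) + 2L
    gaps <- tbar * (1 + rr_jitter * rnorm(m))
    gaps <- pmax(gaps, 0.4 * tbar)
    beats <- -2 * tbar + c(0, cumsum(gaps))
    beats <- beats[beats <= dur + 2 * tbar]
    k <- length(beats)
    amps <- amp_scale * exp(p$amp_jitter * rnorm(k) - p$amp_jitter^2 / 2)

    s_rise <- 0.10 * tbar
    s_fall <- s_rise * (1 + p$pulse_skew)
    s_notch <- 0.08 * tbar
    notch_t <- p$notch_delay * tbar

    x <- numeric(n)
    t0 <- (seq_len(n) - 1) / fs
    for (i in seq_len(k)) {
      lo <- max(1L, floor((beats[i] - 5 * s_rise) * fs) + 1L)
      hi <- min(n, ceiling((beats[i] + notch_t + 5 * s_notch) * fs) + 1L)
      if (lo > n || hi < 1L || lo > hi) next
      tt <- t0[lo:hi] - beats[i]
      sig <- ifelse(tt < 0, s_rise, s_fall)
      pulse <- amps[i] * exp(-tt^2 / (2 * sig^2)) +
        p$notch_amp * amps[i] * exp(-(tt - notch_t)^2 / (2 * s_notch^2))
      x[lo:hi] <- x[lo:hi] + pulse
    }
    x + offset +
      p$baseline_amp * sin(2 * pi * p$baseline_freq * t0) +
      p$noise_sd * rnorm(n)
  })

  structure(list(subject_id = sprintf("subj%03d", subject_index),
                 label = label, fs = fs, samples = samples),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record %s [%s], %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Plot a PPG record waveform
#'
#' @param object A `ppg_record`.
#' @param seconds How many seconds from the start to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ppg_record <- function(object, seconds = 10, ...) {
  n <- min(length(object$samples), round(seconds * object$fs))
  df <- tibble(time = (seq_len(n) - 1) / object$fs,
               amplitude = object$samples[seq_len(n)])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("%s (%s)", object$subject_id, object$label))
}

#' Generate a synthetic two-class PPG cohort
#'
#' Produces `n_normal + n_cvd` records with cohort-wide subject indices
#' (normal subjects first), each deterministic under the spec's root seed.
#'
#' @param spec A [synth_spec()].
#' @return A tibble with columns `subject_id`, `label`, `fs` and a `samples`
#'   list-column of numeric waveforms.
#' @examples
#' cohort <- generate_cohort(synth_spec(n_normal = 2, n_cvd = 2, n_segments = 3))
#' nrow(cohort)
#' @export
generate_cohort <- function(spec) {
  validate_synth_spec(spec)
  if (spec$n_normal < 1) abort("`n_normal` must be at least 1")
  if (spec$n_cvd < 1) abort("`n_cvd` must be at least 1")
  labels <- c(rep("normal", spec$n_normal), rep("cvd", spec$n_cvd))
  recs <- map(seq_along(labels), function(i) {
    generate_record(spec, labels[i], i)
  })
  tibble(subject_id = map_chr(recs, "subject_id"),
         label = labels,
         fs = spec$fs,
         samples = map(recs, "samples"))
}

#' Write a cohort to disk as delimited text plus a manifest
#'
#' Each record becomes one plain-text file (one amplitude per line); the
#' manifest CSV lists `subject_id,label,path,fs`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; the manifest is written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".txt"))
  for (i in seq_len(nrow(cohort))) {
    writeLines(format(cohort$samples[[i]], digits = 15, trim = TRUE,
                      scientific = FALSE), paths[i])
  }
  manifest <- tibble(subject_id = cohort$subject_id, label = cohort$label,
                     path = paths, fs = cohort$fs)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path Path to a manifest CSV written by [write_cohort()]
#'   (columns `subject_id,label,path,fs`; paths relative to the manifest's
#'   directory are resolved against it).
#' @return A cohort tibble as produced by [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste0("manifest not found: ", manifest_path))
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE, comment = "#")
  need <- c("subject_id", "label", "path", "fs")
  if (!all(need %in% names(man))) {
    abort("manifest must have columns subject_id, label, path, fs")
  }
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(man$path), man$path, file.path(base, basename(man$path)))
  samples <- map(paths, function(p) {
    if (!file.exists(p)) abort(paste0("record file not found: ", p))
    as.numeric(readLines(p))
  })
  tibble(subject_id = man$subject_id, label = man$label, fs = man$fs,
         samples = samples)
}
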