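#' Pipeline run configuration
#'
#' Bundles everything the staged pipeline needs: output directory, root
#' seed, synthetic-cohort block, optimizer and classifier selections and
#' their budgets. `read_run_config()` loads the same structure from YAML.
#'
#' @param out_dir Directory all stages read from / write to.
#' @param seed Root seed; every stochastic step derives its stream from it.
#' @param synth Named list of [synth_spec()] arguments (without `seed`).
#' @param optimizers Character subset of `DS, SFLA, WS, AMO`.
#' @param classifiers Character subset of the [fit_predict()] bank.
#' @param folds Cross-validation folds.
#' @param L Reduced value-vector length.
#' @param opt_NP,opt_iter Population size and iteration budget for the
#'   stream optimizers.
#' @param group_by_patient Patient-grouped CV folds?
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, synth = list(),
                       optimizers = c("DS", "SFLA", "WS", "AMO"),
                       classifiers = .fz_classifiers,
                       folds = 10, L = 375, opt_NP = 20, opt_iter = 60,
                       group_by_patient = FALSE) {
  optimizers <- match.arg(optimizers, several.ok = TRUE)
  classifiers <- match.arg(classifiers, .fz_classifiers, several.ok = TRUE)
  if (L %% 5 != 0) abort("`L` must be a multiple of 5 (five frames per patient)")
  structure(list(out_dir = out_dir, seed = seed, synth = synth,
                 optimizers = optimizers, classifiers = classifiers,
                 folds = folds, L = L, opt_NP = opt_NP, opt_iter = opt_iter,
                 group_by_patient = isTRUE(group_by_patient)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config()` (paths relative
#'   to the YAML's directory are kept as written).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$out_dir)) abort("config field `out_dir` is required")
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

.fz_stamp <- function(cfg) {
  # fingerprint of the scientific configuration; the output path is not
  # part of what the run depends on
  core <- unclass(cfg)
  core$out_dir <- NULL
  sprintf("fuzzppg config=%s seed=%s", .fz_hash(core), cfg$seed)
}

.fz_write_stage <- function(df, path, cfg) {
  writeLines(paste0("# ", .fz_stamp(cfg)), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.fz_need <- function(path, stage) {
  if (!file.exists(path)) {
    abort(paste0("missing ", path, "; run stage `", stage, "` first"))
  }
  path
}

.fz_spec_of <- function(cfg) {
  do.call(synth_spec, c(cfg$synth, list(seed = cfg$seed)))
}

#' Pipeline stages
#'
#' Each stage reads its predecessor's CSV outputs from `cfg$out_dir` and
#' writes its own, stamped with a config hash and the seed:
#' `cmd_generate()` writes per-subject record files and `manifest.csv`;
#' `cmd_features()` writes `features.csv`; `cmd_encode()` writes
#' `codewords.csv`; `cmd_optimize()` writes one `optimized_<ALG>.csv` per
#' selected optimizer; `cmd_classify()` writes one `report_<ALG>.csv`;
#' `cmd_report()` aggregates them into `report.csv` (optimizer x
#' classifier x class). Missing upstream files abort with a message naming
#' the stage to run.
#'
#' @param cfg A [run_config()].
#' @return The written path(s), invisibly.
#' @export
cmd_generate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(.fz_spec_of(cfg))
  rec_dir <- file.path(cfg$out_dir, "records")
  man <- write_cohort(cohort, rec_dir)
  path <- file.path(cfg$out_dir, "manifest.csv")
  .fz_write_stage(man, path, cfg)
}

#' @rdname cmd_generate
#' @export
cmd_features <- function(cfg) {
  man <- .fz_need(file.path(cfg$out_dir, "manifest.csv"), "generate")
  cohort <- read_cohort(man)
  feats <- ppg_features(cohort)
  .fz_write_stage(feats, file.path(cfg$out_dir, "features.csv"), cfg)
}

#' @rdname cmd_generate
#' @export
cmd_encode <- function(cfg) {
  fp <- .fz_need(file.path(cfg$out_dir, "features.csv"), "features")
  words <- fuzzy_encode(read_features(fp))
  .fz_write_stage(words, file.path(cfg$out_dir, "codewords.csv"), cfg)
}

#' @rdname cmd_generate
#' @export
cmd_optimize <- function(cfg) {
  wp <- .fz_need(file.path(cfg$out_dir, "codewords.csv"), "encode")
  words <- read_codewords(wp)
  paths <- character(0)
  for (ai in seq_along(cfg$optimizers)) {
    alg <- cfg$optimizers[ai]
    vecs <- optimize_cohort(words, alg, L = cfg$L, NP = cfg$opt_NP,
                            max_iter = cfg$opt_iter,
                            seed = cfg$seed + 1000 * ai)
    long <- tidyr::unnest(
      dplyr::mutate(vecs, position = map(.data$values, seq_along)),
      c("values", "position"))
    long <- dplyr::select(long, "subject_id", "label", "position",
                          value = "values")
    p <- file.path(cfg$out_dir, paste0("optimized_", alg, ".csv"))
    .fz_write_stage(long, p, cfg)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname cmd_generate
#' @export
cmd_classify <- function(cfg) {
  wp <- .fz_need(file.path(cfg$out_dir, "codewords.csv"), "encode")
  words <- read_codewords(wp)
  targets <- class_target_values(words)
  paths <- character(0)
  for (alg in cfg$optimizers) {
    op <- .fz_need(file.path(cfg$out_dir, paste0("optimized_", alg, ".csv")),
                   "optimize")
    long <- readr::read_csv(op, show_col_types = FALSE, comment = "#")
    vecs <- long %>%
      dplyr::arrange(.data$subject_id, .data$position) %>%
      dplyr::group_by(.data$subject_id, .data$label) %>%
      dplyr::summarise(values = list(.data$value), .groups = "drop")
    inst <- frame_instances(vecs, frame_length = cfg$L / 5)
    rep <- map(cfg$classifiers, function(cl) {
      r <- cross_validate(inst, cl, folds = cfg$folds, seed = cfg$seed,
                          target_values = targets,
                          group_by_patient = cfg$group_by_patient)
      dplyr::bind_cols(tibble(optimizer = alg, classifier = cl),
                       as_tibble(r))
    })
    p <- file.path(cfg$out_dir, paste0("report_", alg, ".csv"))
    .fz_write_stage(bind_rows(rep), p, cfg)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname cmd_generate
#' @export
cmd_report <- function(cfg) {
  parts <- map(cfg$optimizers, function(alg) {
    p <- .fz_need(file.path(cfg$out_dir, paste0("report_", alg, ".csv")),
                  "classify")
    readr::read_csv(p, show_col_types = FALSE, comment = "#")
  })
  .fz_write_stage(bind_rows(parts), file.path(cfg$out_dir, "report.csv"),
                  cfg)
}

#' Class-wise modal target code values
#'
#' For each class, the position-wise modal target code over all its code
#' words, returned as the named value vector used as the MSE target
#' coding.
#'
#' @param words Code-word tibble with `label` and `letters`.
#' @return Named numeric vector `c(normal = , cvd = )`.
#' @export
class_target_values <- function(words) {
  vapply(setNames(.fz_labels, .fz_labels), function(cl) {
    target_code(words$letters[words$label == cl])$value
  }, numeric(1))
}

#' Optimize every patient's code-word stream
#'
#' Runs one metaheuristic per subject over its code-word values, seeding
#' each subject's search with its reduced value vector and a
#' subject-specific RNG stream.
#'
#' @param words Code-word tibble from [fuzzy_encode()].
#' @param algorithm `DS`, `SFLA`, `WS` or `AMO`.
#' @param L Representative-vector length.
#' @param NP,max_iter Optimizer budget.
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @return A tibble `subject_id, label, fitness, values` (list-column of
#'   length-`L` optimized vectors).
#' @export
optimize_cohort <- function(words, algorithm = "WS", L = 375, NP = 20,
                            max_iter = 60, seed = 1) {
  subjects <- unique(words$subject_id)
  rows <- map(seq_along(subjects), function(i) {
    sub <- words[words$subject_id == subjects[i], ]
    cfg <- optimizer_config(algorithm, NP = NP, max_iter = max_iter,
                            seed = seed + i)
    res <- optimize_stream(sub, cfg, L = L)
    tibble(subject_id = subjects[i], label = sub$label[1],
           fitness = res$best_fitness, values = list(res$best_position))
  })
  bind_rows(rows)
}

#' Run the whole pipeline in memory
#'
#' generate -> features -> fuzzy encode -> optimize -> classify, returning
#' the aggregated report plus the intermediate tables. Deterministic given
#' the spec (including its seed).
#'
#' @param spec A [synth_spec()].
#' @param optimizers,classifiers Algorithm selections.
#' @param folds,L,opt_NP,opt_iter As in [run_config()].
#' @param group_by_patient Patient-grouped CV folds?
#' @return A list: `words` (code-word tibble), `targets` (class target
#'   values), `vectors` (per optimizer, optimized value tibbles), `report`
#'   (optimizer x classifier x class metric rows).
#' @export
run_ppg_pipeline <- function(spec = synth_spec(),
                             optimizers = "WS",
                             classifiers = .fz_classifiers,
                             folds = 10, L = 375, opt_NP = 20,
                             opt_iter = 60, group_by_patient = FALSE) {
  if (L %% 5 != 0) abort("`L` must be a multiple of 5 (five frames per patient)")
  cohort <- generate_cohort(spec)
  feats <- ppg_features(cohort)
  words <- fuzzy_encode(feats)
  targets <- class_target_values(words)
  vectors <- list()
  reports <- list()
  for (ai in seq_along(optimizers)) {
    alg <- optimizers[ai]
    vecs <- optimize_cohort(words, alg, L = L, NP = opt_NP,
                            max_iter = opt_iter,
                            seed = spec$seed + 1000 * ai)
    vectors[[alg]] <- vecs
    inst <- frame_instances(vecs, frame_length = L / 5)
    reports[[alg]] <- bind_rows(map(classifiers, function(cl) {
      r <- cross_validate(inst, cl, folds = folds, seed = spec$seed,
                          target_values = targets,
                          group_by_patient = group_by_patient)
      dplyr::bind_cols(tibble(optimizer = alg, classifier = cl),
                       as_tibble(r))
    }))
  }
  list(words = words, targets = targets, vectors = vectors,
       report = bind_rows(reports))
}
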