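# Linguistic ranges for the five risk sets of each feature. These are the
# edges of the triangular membership functions of the type-1 system; the
# apex is taken at the range midpoint, the Very Low set carries a left
# shoulder and Very High a right shoulder.
.fz_ranges <- list(
  energy   = list(VL = c(0, 0.1),  L = c(0.7, 3.6),   M = c(2.9, 8.2),  H = c(7.6, 11),    VH = c(9.2, 30)),
  variance = list(VL = c(0, 0.3),  L = c(0.15, 0.45), M = c(0.4, 2.2),  H = c(1.6, 4.3),   VH = c(3.8, 15)),
  apen     = list(VL = c(0, 1.8),  L = c(1, 2.2),     M = c(2, 3.6),    H = c(3.2, 5),     VH = c(4.3, 12)),
  mean     = list(VL = c(0, 2),    L = c(1, 5),       M = c(4, 10),     H = c(7, 16),      VH = c(15, 28)),
  std      = list(VL = c(0, 2),    L = c(1, 4.5),     M = c(4, 9),      H = c(7, 11.6),    VH = c(10, 13)),
  skewness = list(VL = c(0, 0.3),  L = c(0.15, 0.45), M = c(0.4, 2.4),  H = c(1.8, 4.6),   VH = c(3.6, 10)),
  kurtosis = list(VL = c(0, 0.05), L = c(0.025, 0.1), M = c(0.09, 0.4), H = c(0.28, 0.64), VH = c(0.54, 1)),
  peak_max = list(VL = c(0, 3),    L = c(1, 5.2),     M = c(4, 9.3),    H = c(7, 11.6),    VH = c(10, 14.6))
)

.fz_sets <- c("VL", "L", "M", "H", "VH")
.fz_outputs <- c("N", "L", "M", "H", "VH")

#' Build the eight feature fuzzifiers
#'
#' One fuzzifier per feature, each a tibble of five linguistic sets
#' (`VL, L, M, H, VH`) with triangular membership functions: the triangle
#' spans the set's numeric range with its peak at the midpoint; `VL` has a
#' left shoulder (membership 1 below its peak) and `VH` a right shoulder.
#'
#' @param ranges Optional replacement range table with the same structure as
#'   the built-in one (a named list of features, each a named list of five
#'   `c(lo, hi)` ranges); used by the YAML config round-trip.
#' @return A named list of fuzzifier tibbles with columns
#'   `set, lo, peak, hi, shoulder`.
#' @examples
#' fz <- build_fuzzifiers()
#' fz$energy  # High spans 7.6-11 with peak 9.3
#' @export
build_fuzzifiers <- function(ranges = NULL) {
  ranges <- ranges %||% .fz_ranges
  if (!all(.fz_features %in% names(ranges))) {
    abort("ranges must define all eight features")
  }
  out <- lapply(ranges[.fz_features], function(rr) {
    if (!identical(names(rr), .fz_sets)) {
      abort("each feature needs sets VL, L, M, H, VH in order")
    }
    lo <- unname(map_dbl(rr, 1))
    hi <- unname(map_dbl(rr, 2))
    if (any(lo > hi)) abort("set ranges must have lo <= hi")
    tibble(set = .fz_sets, lo = lo, peak = (lo + hi) / 2, hi = hi,
           shoulder = c("left", "none", "none", "none", "right"))
  })
  out
}

# Membership of a vector of values in one linguistic set (vectorised).
.fz_membership <- function(x, lo, peak, hi, shoulder) {
  up <- if (peak > lo) (x - lo) / (peak - lo) else as.numeric(x >= lo)
  dn <- if (hi > peak) (hi - x) / (hi - peak) else as.numeric(x <= hi)
  m <- pmax(0, pmin(up, dn, 1))
  if (shoulder == "left") m[x <= peak] <- 1
  if (shoulder == "right") m[x >= peak] <- 1
  m
}

# n x 5 membership matrix for values under one fuzzifier, with the
# nearest-support fallback applied row-wise.
.fz_fuzzify_matrix <- function(x, fz) {
  m <- vapply(seq_len(nrow(fz)), function(i) {
    .fz_membership(x, fz$lo[i], fz$peak[i], fz$hi[i], fz$shoulder[i])
  }, numeric(length(x)))
  m <- matrix(m, nrow = length(x), dimnames = list(NULL, fz$set))
  gap <- rowSums(m) == 0
  if (any(gap)) {
    xg <- x[gap]
    d <- vapply(seq_len(nrow(fz)), function(i) {
      pmax(fz$lo[i] - xg, xg - fz$hi[i], 0)
    }, numeric(length(xg)))
    d <- matrix(d, nrow = length(xg))
    # nearest support; ties broken toward the higher set
    pick <- max.col(-d[, 5:1, drop = FALSE], ties.method = "first")
    pick <- 6L - pick
    mg <- matrix(0, length(xg), 5)
    mg[cbind(seq_along(xg), pick)] <- 1
    m[gap, ] <- mg
  }
  m
}

#' Fuzzify a value over one feature's linguistic sets
#'
#' Returns the membership of `value` in each of the five sets. If the value
#' falls in a coverage gap between two ranges (all raw memberships 0), it is
#' assigned membership 1 in the set whose support is nearest, ties broken
#' toward the higher set.
#'
#' @param value A finite number.
#' @param fuzzifier One element of [build_fuzzifiers()].
#' @return A named numeric vector of five memberships in `[0, 1]`.
#' @examples
#' fz <- build_fuzzifiers()
#' fuzzify(9.3, fz$energy)  # peak of High -> membership 1
#' @export
fuzzify <- function(value, fuzzifier) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort("`value` must be a single finite number")
  }
  drop(.fz_fuzzify_matrix(value, fuzzifier))
}

#' The banded fuzzy associative matrix
#'
#' The 5x5 rule grid pairing the energy sets (rows) with a partner feature's
#' sets (columns). Only the 13 cells on the main diagonal band are defined;
#' the remaining 12 are don't-cares (`NA`) that never fire. The same band is
#' used for all seven energy-vs-partner subsystems (configurable via
#' [fuzzy_config_write()]).
#'
#' @return A 5x5 character matrix with dimnames `VL..VH` x `VL..VH`; entries
#'   are output levels `N, L, M, H, VH` or `NA`.
#' @export
default_fam <- function() {
  m <- matrix(NA_character_, 5, 5, dimnames = list(energy = .fz_sets,
                                                   partner = .fz_sets))
  m["VL", c("VL", "L")] <- c("N", "L")
  m["L",  c("VL", "L", "M")] <- c("L", "L", "M")
  m["M",  c("L", "M", "H")] <- c("M", "M", "H")
  m["H",  c("M", "H", "VH")] <- c("H", "H", "VH")
  m["VH", c("H", "VH")] <- c("VH", "VH")
  m
}

#' Count the defined rules of a FAM
#'
#' @param fam A 5x5 character matrix as from [default_fam()]; `NA` cells are
#'   don't-cares.
#' @return Number of defined (non-don't-care) cells.
#' @examples
#' count_active_rules(default_fam())  # 13
#' @export
count_active_rules <- function(fam) {
  sum(!is.na(fam))
}

# Mamdani inference for all rows at once: me, mp are n x 5 membership
# matrices for energy and the partner. Returns integer output level 1..5
# (N..VH). Conjunction = min, aggregation = max, defuzzification = argmax
# level with ties toward the higher risk. Rows where no rule fires fall
# back to the defined cell nearest the (argmax energy, argmax partner)
# cell within the energy row band.
.fz_infer_matrix <- function(me, mp, fam) {
  n <- nrow(me)
  agg <- matrix(0, n, 5, dimnames = list(NULL, .fz_outputs))
  cells <- which(!is.na(fam), arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    out <- match(fam[i, j], .fz_outputs)
    fire <- pmin(me[, i], mp[, j])
    agg[, out] <- pmax(agg[, out], fire)
  }
  # argmax with ties -> higher level: scan reversed columns, take first max
  lev <- 6L - max.col(agg[, 5:1, drop = FALSE], ties.method = "first")
  dead <- rowSums(agg) == 0
  if (any(dead)) {
    for (r in which(dead)) {
      ei <- 6L - which.max(rev(me[r, ]))
      pj <- 6L - which.max(rev(mp[r, ]))
      defd <- which(!is.na(fam[ei, ]))
      if (length(defd) == 0) defd <- which(!is.na(fam), arr.ind = TRUE)[, 2]
      j <- defd[order(abs(defd - pj), -defd)][1]
      lev[r] <- match(fam[ei, j], .fz_outputs)
    }
  }
  lev
}

#' Infer one subsystem output level
#'
#' Evaluates one two-input Mamdani subsystem: energy paired with one partner
#' feature through the FAM. Rule firing is `min(energy membership, partner
#' membership)` over the defined cells, aggregated per output level by max;
#' the returned level is the argmax, ties broken toward the higher risk.
#'
#' @param energy_value,partner_value Finite input values (on the linguistic
#'   scale, i.e. after any feature scaling).
#' @param partner_fuzzifier The partner feature's fuzzifier.
#' @param fam Rule grid, default [default_fam()].
#' @param energy_fuzzifier Energy fuzzifier, default from
#'   [build_fuzzifiers()].
#' @return One of `"N", "L", "M", "H", "VH"`.
#' @examples
#' fz <- build_fuzzifiers()
#' infer_pair(5.55, 1.3, fz$variance)  # both at their M peaks -> "M"
#' @export
infer_pair <- function(energy_value, partner_value, partner_fuzzifier,
                       fam = default_fam(),
                       energy_fuzzifier = build_fuzzifiers()$energy) {
  me <- .fz_fuzzify_matrix(energy_value, energy_fuzzifier)
  mp <- .fz_fuzzify_matrix(partner_value, partner_fuzzifier)
  .fz_outputs[.fz_infer_matrix(me, mp, fam)]
}

#' Encode a feature table into code words
#'
#' Runs the bank of seven fuzzy subsystems (energy paired with each of the
#' other seven features) on every segment row and encodes the seven output
#' levels as a code-word letter string with its numeric value. Features are
#' first mapped onto the linguistic scale by `scaling` (see
#' [default_feature_scaling()]).
#'
#' @param features Feature tibble from [ppg_features()].
#' @param fuzzifiers From [build_fuzzifiers()].
#' @param fam Rule grid shared by the seven subsystems, or a named list with
#'   one grid per partner feature.
#' @param scaling Feature-scaling tibble; use [identity_feature_scaling()]
#'   for already-calibrated inputs.
#' @return A tibble `subject_id, label, segment, letters, value`, one row
#'   per segment; letter positions follow the partner order
#'   variance, apen, mean, std, skewness, kurtosis, peak_max.
#' @export
fuzzy_encode <- function(features, fuzzifiers = build_fuzzifiers(),
                         fam = default_fam(),
                         scaling = default_feature_scaling()) {
  need <- c("subject_id", "label", "segment", .fz_features)
  if (!all(need %in% names(features))) {
    abort("`features` must carry subject_id, label, segment and the eight features")
  }
  scaled <- scale_features(features, scaling)
  me <- .fz_fuzzify_matrix(scaled$energy, fuzzifiers$energy)
  fams <- if (is.list(fam)) fam else setNames(rep(list(fam), 7), .fz_partners)
  lev <- matrix(0L, nrow(scaled), 7)
  for (k in seq_along(.fz_partners)) {
    p <- .fz_partners[k]
    mp <- .fz_fuzzify_matrix(scaled[[p]], fuzzifiers[[p]])
    lev[, k] <- .fz_infer_matrix(me, mp, fams[[p]])
  }
  letters5 <- c("A", "B", "C", "D", "E")
  mat <- matrix(letters5[lev], nrow(scaled), 7)
  words <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  tibble(subject_id = features$subject_id, label = features$label,
         segment = features$segment, letters = words,
         value = codeword_value(words))
}

#' Export / import the fuzzifier table and FAM as YAML
#'
#' Lets users re-band the rule grid or move the linguistic ranges without
#' code changes. The file holds the eight range tables and the FAM rows
#' (don't-cares as `"x"`).
#'
#' @param path YAML file path.
#' @param fuzzifiers,fam Objects as produced by [build_fuzzifiers()] and
#'   [default_fam()].
#' @return `fuzzy_config_write()` returns `path` invisibly;
#'   `fuzzy_config_read()` a list with elements `fuzzifiers` and `fam`.
#' @export
fuzzy_config_write <- function(path, fuzzifiers = build_fuzzifiers(),
                               fam = default_fam()) {
  ranges <- lapply(fuzzifiers, function(fz) {
    setNames(lapply(seq_len(nrow(fz)), function(i) c(fz$lo[i], fz$hi[i])),
             fz$set)
  })
  fam_rows <- apply(fam, 1, function(r) {
    unname(ifelse(is.na(r), "x", r))
  }, simplify = FALSE)
  yaml::write_yaml(list(ranges = ranges, fam = fam_rows), path)
  invisible(path)
}

#' @rdname fuzzy_config_write
#' @export
fuzzy_config_read <- function(path) {
  if (!file.exists(path)) abort(paste0("fuzzy config not found: ", path))
  cfg <- yaml::read_yaml(path)
  fuzzifiers <- build_fuzzifiers(cfg$ranges)
  fam <- do.call(rbind, lapply(cfg$fam, unlist))
  dimnames(fam) <- list(energy = .fz_sets, partner = .fz_sets)
  fam[fam == "x"] <- NA_character_
  bad <- !is.na(fam) & !fam %in% .fz_outputs
  if (any(bad)) abort("FAM entries must be N, L, M, H, VH or x")
  list(fuzzifiers = fuzzifiers, fam = fam)
}
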