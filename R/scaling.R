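# Feature calibration block.
#
# The raw segment statistics live on physical scales (energy is a raw sum
# of squares over 200 samples, so it is orders of magnitude above the
# linguistic ranges), while the linguistic sets are defined on the fixed
# numeric domains of the fuzzifier table. One affine map per feature
# (scaled = scale * raw + offset) bridges the two. The constants below were
# calibrated once against the default synthetic cohort so that >= 95% of
# segments land inside the union of the linguistic ranges and the two
# classes populate different risk bands; they are the single tuning block
# of the generator-to-fuzzifier interface.
.fz_default_scaling <- tibble::tibble(
  feature = c("energy", "variance", "apen", "mean", "std",
              "skewness", "kurtosis", "peak_max"),
  scale   = c(0.0211, 10.39, 11.78, 17.33, 22.91, 5.86, 0.402, 5.32),
  offset  = c(-5.02, -0.655, -3.85, -18.94, -4.20, -3.03, -0.779, -7.65)
)

#' Affine feature-to-linguistic-scale maps
#'
#' `default_feature_scaling()` returns the calibrated per-feature affine
#' maps (`scaled = scale * raw + offset`) that place the default synthetic
#' cohort's raw features onto the linguistic domains of the fuzzifier
#' table. `identity_feature_scaling()` returns the no-op map for inputs
#' that already live on the linguistic scale.
#'
#' @return A tibble with columns `feature`, `scale`, `offset`.
#' @export
default_feature_scaling <- function() {
  .fz_default_scaling
}

#' @rdname default_feature_scaling
#' @export
identity_feature_scaling <- function() {
  tibble(feature = .fz_features, scale = 1, offset = 0)
}

#' Apply a feature-scaling map
#'
#' @param features Feature tibble with the eight feature columns.
#' @param scaling Scaling tibble as from [default_feature_scaling()].
#' @return The tibble with the feature columns affinely rescaled.
#' @export
scale_features <- function(features, scaling = default_feature_scaling()) {
  if (!all(c("feature", "scale", "offset") %in% names(scaling))) {
    abort("`scaling` needs columns feature, scale, offset")
  }
  for (i in seq_len(nrow(scaling))) {
    f <- scaling$feature[i]
    if (f %in% names(features)) {
      features[[f]] <- scaling$scale[i] * features[[f]] + scaling$offset[i]
    }
  }
  features
}
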