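# Staining quantification in the deconvoluted (HEM, DAB) plane: tissue /
# positive / negative-nucleus segmentation by simple thresholds, and the
# two pathologist features -- Labelling Index (LI, % of tissue or nucleus
# area that is DAB-positive) and Quick Score (QS, LI times the mean DAB
# darkness of positive pixels, i.e. the mean with negatives zero-set).
# An efficient normalisation lets segmentation parameters set on the
# target batch be reused unchanged on every other batch.

#' Segmentation parameters
#'
#' @param dab_threshold minimum DAB (brown) coefficient for a positive
#'   pixel.
#' @param dab_over_hem_factor a positive pixel's brown value must also
#'   exceed this factor times its blue value.
#' @param tissue_radius tissue pixels have `(hem, dab)` distance to the
#'   origin above this radius (default 0.015, a small value appropriate
#'   for standardised acquisition).
#' @param hem_nucleus_threshold minimum HEM coefficient identifying
#'   negative (blue) nuclei; required for nuclear markers only.
#' @param min_denominator_px cores with fewer denominator pixels are
#'   flagged unreliable (default 50).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(dab_threshold,
                                dab_over_hem_factor,
                                tissue_radius = 0.015,
                                hem_nucleus_threshold = NULL,
                                min_denominator_px = 50L) {
  stopifnot(dab_threshold >= 0, dab_over_hem_factor >= 0, tissue_radius >= 0,
            is.null(hem_nucleus_threshold) || hem_nucleus_threshold >= 0)
  structure(list(tissue_radius = tissue_radius,
                 dab_threshold = dab_threshold,
                 dab_over_hem_factor = dab_over_hem_factor,
                 hem_nucleus_threshold = hem_nucleus_threshold,
                 min_denominator_px = as.integer(min_denominator_px)),
            class = "segmentation_params")
}

#' Segment tissue, positive staining and nuclei
#'
#' In the deconvoluted plane: tissue pixels lie outside a disc of radius
#' `tissue_radius` centred at the origin; positive pixels are tissue whose
#' brown value exceeds both `dab_threshold` and `dab_over_hem_factor`
#' times their blue value.  For nuclear markers the nucleus area is the
#' union of positive (brown) nuclei and blue nuclei above
#' `hem_nucleus_threshold`.
#'
#' @param dec a clipped `deconvolved_image` (see [deconvolve()]).
#' @param params a [segmentation_params()].
#' @param nuclear is the marker nuclear?  Requires
#'   `hem_nucleus_threshold`.
#' @return list of logical masks `tissue`, `positive`, and (if nuclear)
#'   `nucleus`.
#' @export
segment_stains <- function(dec, params, nuclear = FALSE) {
  stopifnot(inherits(dec, "deconvolved_image"), inherits(params, "segmentation_params"))
  if (!dec$clipped)
    stop("segmentation requires a clipped (nonnegative) deconvolved image")
  tissue <- sqrt(dec$hem^2 + dec$dab^2) > params$tissue_radius
  positive <- tissue & dec$dab > params$dab_threshold &
    dec$dab > params$dab_over_hem_factor * dec$hem
  out <- list(tissue = tissue, positive = positive)
  if (nuclear) {
    if (is.null(params$hem_nucleus_threshold))
      stop("nuclear markers require hem_nucleus_threshold")
    out$nucleus <- positive | (tissue & dec$hem > params$hem_nucleus_threshold)
  }
  out
}

#' Labelling Index and Quick Score
#'
#' `labelling_index` is the percentage of denominator pixels (tissue, or
#' nucleus for nuclear markers) that are positive.  `quick_score` is the
#' LI (as a fraction) times the mean DAB darkness over positive pixels --
#' equivalently the mean DAB darkness over the denominator with negative
#' pixels zero-set.  QS is reported unitless on that fraction scale.
#'
#' @param masks mask list from [segment_stains()].
#' @param dec the matching `deconvolved_image` (for `quick_score`).
#' @param nuclear use the nucleus mask as denominator?
#' @return `labelling_index`: percentage in `[0, 100]`; `quick_score`:
#'   nonnegative scalar.
#' @export
labelling_index <- function(masks, nuclear = FALSE) {
  denom <- if (nuclear) masks$nucleus else masks$tissue
  n_denom <- sum(denom)
  if (n_denom == 0L) stop("undefined feature: empty denominator mask")
  100 * sum(masks$positive) / n_denom
}

#' @rdname labelling_index
#' @export
quick_score <- function(masks, dec, nuclear = FALSE) {
  denom <- if (nuclear) masks$nucleus else masks$tissue
  n_denom <- sum(denom)
  if (n_denom == 0L) stop("undefined feature: empty denominator mask")
  sum(dec$dab[masks$positive]) / n_denom
}

#' Per-core staining features
#'
#' Computes the segmentation masks once over a deconvolved tiled reference
#' and aggregates LI and QS per tile (= per tissue core).  Cores whose
#' denominator is empty get `NA` features; cores below
#' `min_denominator_px` are flagged unreliable.  Both should be excluded
#' from distribution tests.
#'
#' @param tiled the `tiled_reference` the deconvolution came from.
#' @param dec a clipped `deconvolved_image` of `tiled$image`.
#' @param params a [segmentation_params()].
#' @param nuclear is the marker nuclear?
#' @return data.frame with columns `core_id`, `li`, `qs`, `n_tissue_px`,
#'   `n_positive_px`, `n_nucleus_px`, `reliable`.
#' @export
per_core_features <- function(tiled, dec, params, nuclear = FALSE) {
  stopifnot(inherits(tiled, "tiled_reference"))
  if (!identical(dim(dec$hem), dim(unclass(tiled$image))[1:2]))
    stop("deconvolved image does not match the tiled reference geometry")
  masks <- segment_stains(dec, params, nuclear)
  tp <- tiled$tile_px
  rows <- lapply(seq_len(tiled$n_tiles), function(i) {
    r0 <- tiled$tile_origins[i, 1]; c0 <- tiled$tile_origins[i, 2]
    ri <- r0:(r0 + tp - 1L); ci <- c0:(c0 + tp - 1L)
    tis <- masks$tissue[ri, ci]
    pos <- masks$positive[ri, ci]
    nuc <- if (nuclear) masks$nucleus[ri, ci] else NULL
    denom_n <- if (nuclear) sum(nuc) else sum(tis)
    li <- qs <- NA_real_
    if (denom_n > 0L) {
      li <- 100 * sum(pos) / denom_n
      qs <- sum(dec$dab[ri, ci][pos]) / denom_n
    }
    data.frame(core_id = i, li = li, qs = qs,
               n_tissue_px = sum(tis), n_positive_px = sum(pos),
               n_nucleus_px = if (nuclear) sum(nuc) else NA_integer_,
               reliable = denom_n >= params$min_denominator_px)
  })
  do.call(rbind, rows)
}

#' Compare LI or QS distributions between two batches
#'
#' Two-sample KS test on a per-core feature across batches, with the
#' summary statistics (means, SDs) reported alongside.  Consecutive TMA
#' slices carry near-identical biology, so after efficient normalisation
#' the feature distributions should not differ significantly.
#'
#' @param a,b per-core feature data.frames from [per_core_features()]
#'   (unreliable / NA cores are dropped).
#' @param feature `"li"` or `"qs"`.
#' @return data.frame with one row: `feature`, `ks_stat`, `ks_pvalue`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
compare_feature_distributions <- function(a, b, feature = c("li", "qs")) {
  feature <- match.arg(feature)
  va <- a[[feature]][a$reliable & !is.na(a[[feature]])]
  vb <- b[[feature]][b$reliable & !is.na(b[[feature]])]
  if (length(va) == 0L || length(vb) == 0L)
    stop("no reliable cores to compare")
  kt <- ks_test(va, vb)
  data.frame(feature = feature,
             ks_stat = kt$statistic, ks_pvalue = kt$p.value,
             mean_a = mean(va), mean_b = mean(vb),
             sd_a = stats::sd(va), sd_b = stats::sd(vb),
             n_a = length(va), n_b = length(vb),
             stringsAsFactors = FALSE)
}
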