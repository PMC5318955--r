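make_dec <- function(hem, dab, clipped = TRUE) {
  u <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
  v <- c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2))
  structure(list(hem = hem, dab = dab,
                 residual = matrix(0, nrow(hem), ncol(hem)),
                 basis = stain_basis(u, v), clipped = clipped),
            class = "deconvolved_image")
}

test_that("segmentation applies the disc, threshold and factor rules", {
  hem <- matrix(c(0,    0.01, 0.5, 0.1), 2, 2)
  dab <- matrix(c(0,    0.012, 0.1, 0.6), 2, 2)
  dec <- make_dec(hem, dab)
  p <- segmentation_params(dab_threshold = 0.15, dab_over_hem_factor = 0.5)
  m <- segment_stains(dec, p)
  expect_identical(m$tissue, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  # (0.5, 0.1): tissue but 0.1 < 0.15 -> not positive; (0.1, 0.6): positive
  expect_identical(m$positive, matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))

  # nuclear markers add blue nuclei to the denominator mask
  pn <- segmentation_params(dab_threshold = 0.15, dab_over_hem_factor = 0.5,
                            hem_nucleus_threshold = 0.3)
  mn <- segment_stains(dec, pn, nuclear = TRUE)
  expect_identical(mn$nucleus, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))

  expect_error(segment_stains(make_dec(hem, dab, clipped = FALSE), p),
               "clipped")
  expect_error(segment_stains(dec, p, nuclear = TRUE), "hem_nucleus_threshold")

  # monotone: raising the DAB threshold never gains positives
  set.seed(59)
  dec2 <- make_dec(matrix(runif(400, 0, 0.8), 20), matrix(runif(400, 0, 0.8), 20))
  counts <- sapply(seq(0, 0.8, by = 0.05), function(thr) {
    pp <- segmentation_params(dab_threshold = thr, dab_over_hem_factor = 0.25)
    sum(segment_stains(dec2, pp)$positive)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("LI and QS follow the zero-setting definition", {
  # 3 tissue pixels, 1 positive with dab 0.6: li = 33.33, qs = mean(0.6, 0, 0)
  hem <- matrix(c(0.5, 0.5, 0.05, 0), 2, 2)
  dab <- matrix(c(0.01, 0.02, 0.6, 0), 2, 2)
  dec <- make_dec(hem, dab)
  p <- segmentation_params(dab_threshold = 0.15, dab_over_hem_factor = 0.5)
  m <- segment_stains(dec, p)
  expect_equal(sum(m$tissue), 3)
  expect_equal(labelling_index(m), 100 / 3, tolerance = 1e-12)
  expect_equal(quick_score(m, dec), 0.2, tolerance = 1e-12)

  # all positive -> li 100; none positive -> li 0, qs 0
  all_pos <- make_dec(matrix(0.05, 2, 2), matrix(0.7, 2, 2))
  m2 <- segment_stains(all_pos, p)
  expect_equal(labelling_index(m2), 100)
  none <- make_dec(matrix(0.7, 2, 2), matrix(0.01, 2, 2))
  m3 <- segment_stains(none, p)
  expect_equal(labelling_index(m3), 0)
  expect_equal(quick_score(m3, none), 0)

  empty <- make_dec(matrix(0, 2, 2), matrix(0, 2, 2))
  m4 <- segment_stains(empty, p)
  expect_error(labelling_index(m4), "empty denominator")
})

test_that("per-core features aggregate one row per core and match the truth", {
  spec <- synthetic_spec(n_cores = 94L, tile_px = 30L, seed = 61,
                         noise_sd = 0, glass_noise_sd = 0)
  ref <- generate_reference(spec)
  basis <- stain_basis(spec$v_hem, spec$v_dab)
  dec <- deconvolve(rgb_to_sda(ref$reference$image, ref$background),
                    basis, clip = TRUE)
  generous <- segmentation_params(dab_threshold = 0.02, dab_over_hem_factor = 0)
  feats <- per_core_features(ref$reference, dec, generous)
  expect_equal(nrow(feats), 94)
  expect_equal(feats$li, ref$core_truth$li, tolerance = 1e-6)
  expect_equal(feats$qs, ref$core_truth$qs, tolerance = 1e-3)
  expect_true(all(feats$reliable))

  same <- compare_feature_distributions(feats, feats, "li")
  expect_equal(same$ks_stat, 0)
  expect_equal(same$ks_pvalue, 1)

  # disjoint LI ranges give KS statistic 1
  shifted <- feats
  shifted$li <- shifted$li + 200
  expect_equal(compare_feature_distributions(shifted, feats, "li")$ks_stat, 1)
})
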