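test_that("the fitted transform exposes the standard modelling interface", {
  spec <- small_spec(seed = 91, n_cores = 9L, tile_px = 60L)
  ref <- generate_reference(spec, pixel_truth = FALSE)
  b2 <- perturb_batch(spec, batch_perturbation(rotation_deg_hem = 6,
                                               rotation_deg_dab = -6),
                      pixel_truth = FALSE)
  sn <- stain_norm(b2$reference, ref$reference,
                   config = extraction_config(sample_fraction = 0.2),
                   n_quantiles = 300)
  expect_s3_class(sn, "stain_norm")
  expect_output(print(sn), "after matching")
  sm <- summary(sn)
  expect_output(print(sm), "quality control")
  expect_true(all(c("stage", "channel", "rmse", "ks_stat") %in% names(sm$qc_table)))
  co <- coef(sn)
  expect_identical(dim(co$source), c(3L, 3L))
  expect_true(length(residuals(sn)) > 100)
  expect_lt(mean(abs(residuals(sn))), 0.05)

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(sn))

  # matching brings the hold-out channel distributions together
  expect_lt(sm$qc_table$ks_stat[sm$qc_table$stage == "after_matching" &
                                sm$qc_table$channel == "hem"],
            sm$qc_table$ks_stat[sm$qc_table$stage == "before_matching" &
                                sm$qc_table$channel == "hem"])

  res <- predict(sn, b2$reference)
  expect_s3_class(res$normalised, "rgb_image")
  expect_s3_class(res$deconvolved, "deconvolved_image")
  expect_identical(dim(res$normalised), dim(b2$reference$image))
})

test_that("normalising the target batch to itself is a no-op", {
  spec <- small_spec(seed = 93, n_cores = 9L, tile_px = 60L,
                     noise_sd = 0, glass_noise_sd = 0)
  ref <- generate_reference(spec, pixel_truth = FALSE)
  sn <- stain_norm(ref$reference, ref$reference,
                   config = extraction_config(sample_fraction = 0.2),
                   n_quantiles = 200)
  out <- predict(sn, ref$reference$image)
  expect_true(all(abs(unclass(out$normalised) - unclass(ref$reference$image)) <= 1))
  # and its hold-out QC is clean at every stage
  tab <- summary(sn)$qc_table
  expect_true(all(tab$ks_stat < 0.01))
  expect_true(all(tab$rmse < 0.01))
})

test_that("the pipeline driver writes the full report bundle", {
  spec <- small_spec(seed = 97, n_cores = 9L, tile_px = 60L)
  ref <- generate_reference(spec, pixel_truth = FALSE)
  b2 <- perturb_batch(spec, batch_perturbation(rotation_deg_hem = 6,
                                               rotation_deg_dab = -6),
                      pixel_truth = FALSE)
  out <- tempfile()
  res <- suppressMessages(run_pipeline(
    list(ref = ref$reference, b2 = b2$reference), target = "ref",
    out_dir = out, config = extraction_config(sample_fraction = 0.2),
    n_quantiles = 200,
    seg_params = segmentation_params(dab_threshold = 0.1,
                                     dab_over_hem_factor = 0.25)))
  expect_true(file.exists(file.path(out, "qc.csv")))
  expect_true(file.exists(file.path(out, "basis_b2.json")))
  expect_true(file.exists(file.path(out, "normalised_b2.tiff")))
  expect_true(file.exists(file.path(out, "features_b2.csv")))
  expect_true(file.exists(file.path(out, "feature_comparisons.csv")))
  expect_setequal(unique(res$qc$stage), c("before_matching", "after_matching"))
  expect_equal(nrow(res$features$b2), 9)
  unlink(out, recursive = TRUE)
})
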