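u <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
v <- c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2))

test_that("deconvolution inverts the stain basis to machine precision", {
  basis <- stain_basis(u, v)
  expect_equal(unname(deconvolve(matrix(basis$a, 1), basis)[1, ]),
               c(1, 0, 0), tolerance = 1e-12)
  mix <- 0.3 * basis$a + 0.7 * basis$b
  expect_equal(unname(deconvolve(matrix(mix, 1), basis)[1, ]),
               c(0.3, 0.7, 0), tolerance = 1e-12)

  set.seed(13)
  cloud <- matrix(runif(3 * 500, 0, 1.5), ncol = 3)
  co <- deconvolve(cloud, basis)
  expect_lt(max(abs(co %*% t(basis$M) - cloud)), 1e-10)

  clipped <- deconvolve(cloud, basis, clip = TRUE)
  expect_true(all(clipped[, c("hem", "dab")] >= 0))
})

test_that("P99 rescaling is homogeneous and can degrade nonlinear deformations", {
  set.seed(17)
  target <- rgamma(20000, 2, scale = 0.3)
  f1 <- fit_p99(target, target)
  expect_equal(f1$params$scale, 1)
  expect_equal(predict(f1, c(0, 0.4, 2)), c(0, 0.4, 2))
  f2 <- fit_p99(2 * target, target)
  expect_equal(f2$params$scale, 0.5, tolerance = 1e-12)
  expect_error(fit_p99(rep(0, 100), target), "degenerate source")

  # a pure gain cannot fix a cubic deformation: the bulk fit degrades
  source <- target + 0.6 * target^3
  f3 <- fit_p99(source, target)
  pre <- qq_rmse(qq_table(source, target))
  post <- qq_rmse(qq_table(predict(f3, source), target))
  expect_gt(post, 0)           # rescaling the P99 does not give identity
  mid <- median(target)
  expect_gt(abs(predict(f3, median(source)) - mid) / mid, 0.1)
})

test_that("quantile matching maps source onto target distributions", {
  set.seed(19)
  target <- rgamma(30000, 2, scale = 0.3)
  f_id <- fit_quantile_match(target, target)
  x <- seq(0.01, 2, length.out = 50)
  expect_equal(predict(f_id, x), x, tolerance = 1e-3)

  shifted <- target + 0.2
  f_sh <- fit_quantile_match(shifted, target)
  bulk <- seq(0.35, 1.2, length.out = 30)
  expect_equal(predict(f_sh, bulk), bulk - 0.2, tolerance = 0.02)

  # CDF matching never increases the KS distance (checked over random draws)
  for (s in 1:5) {
    set.seed(100 + s)
    a <- rgamma(3000, runif(1, 1, 3), scale = runif(1, 0.1, 0.5))
    b <- rgamma(3000, runif(1, 1, 3), scale = runif(1, 0.1, 0.5))
    f <- fit_quantile_match(a, b)
    expect_lte(ks_statistic(predict(f, a), b), ks_statistic(a, b) + 1e-12)
  }
})

test_that("linear quantile regression recovers affine relations", {
  set.seed(23)
  s <- rgamma(20000, 2, scale = 0.25)
  t <- 1.3 * s + 0.05
  f <- fit_linear(s, t)
  expect_equal(f$params$slope, 1.3, tolerance = 1e-6)
  expect_equal(f$params$intercept, 0.05, tolerance = 1e-6)
  f_id <- fit_linear(s, s)
  expect_equal(f_id$params$slope, 1, tolerance = 1e-8)
  expect_equal(f_id$params$intercept, 0, tolerance = 1e-8)
  expect_equal(predict(f, -1), 0)  # floored at zero
  expect_error(fit_linear(rep(0.3, 100), t), "zero variance")
})

test_that("B-spline quantile regression corrects a cubic deformation", {
  set.seed(29)
  target <- 0.05 + rgamma(30000, 2, scale = 0.3)
  source <- target + 0.6 * target^3
  pre <- qq_rmse(qq_table(source, target))
  expect_gte(pre, 0.3)
  f <- fit_bspline(source, target)
  post <- qq_rmse(qq_table(predict(f, source), target))
  expect_lte(post, 0.05)

  # identity data gives the identity map; fitted maps are monotone
  f_id <- fit_bspline(target, target)
  x <- seq(0.06, 1.5, length.out = 200)
  expect_equal(predict(f_id, x), x, tolerance = 1e-2)
  for (ff in list(f, f_id)) {
    y <- predict(ff, seq(0, 3, length.out = 500))
    expect_true(all(diff(y) >= -1e-9))
  }
})

test_that("all fit mappings are monotone and preserve nonnegativity", {
  set.seed(31)
  s <- rgamma(5000, 2, scale = 0.3)
  t <- rgamma(5000, 1.5, scale = 0.4)
  grid <- seq(0, 3, length.out = 400)
  fits <- list(fit_p99(s, t), fit_quantile_match(s, t),
               fit_linear(s, t), fit_bspline(s, t))
  for (f in fits) {
    y <- predict(f, grid)
    expect_true(all(diff(y) >= -1e-9))
    expect_true(all(y >= 0))
  }
  # serialisation round trip preserves the mapping
  p <- tempfile(fileext = ".json")
  write_channel_fits(list(hem = fits[[2]], dab = fits[[4]]), p)
  back <- read_channel_fits(p)
  expect_equal(predict(back$hem, grid), predict(fits[[2]], grid), tolerance = 1e-9)
  expect_equal(predict(back$dab, grid), predict(fits[[4]], grid), tolerance = 1e-9)
  unlink(p)
})

test_that("normalising a noiseless batch to itself is an identity pipeline", {
  spec <- small_spec(seed = 37, n_cores = 9L, tile_px = 60L,
                     noise_sd = 0, glass_noise_sd = 0)
  ref <- generate_reference(spec, pixel_truth = FALSE)
  img <- ref$reference$image
  basis <- extract_stains(ref$reference, "macenko",
                          extraction_config(sample_fraction = 0.3),
                          background = white_bg())
  res <- apply_normalization(img, basis, background = white_bg())
  expect_true(all(abs(unclass(res$normalised) - unclass(img)) <= 1))
})
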