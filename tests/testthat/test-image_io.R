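test_that("PNG and TIFF round trips are bit-exact and bad shapes are rejected", {
  set.seed(1)
  img <- rgb_image(array(sample(0:255, 20 * 30 * 3, TRUE), c(20, 30, 3)))
  for (ext in c("png", "tiff")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_image(img, p)
    back <- read_image(p)
    expect_identical(unclass(back)[, , ], unclass(img)[, , ])
    unlink(p)
  }
  # 2x2 white PNG reads as all-255
  p <- tempfile(fileext = ".png")
  png::writePNG(array(1, c(2, 2, 3)), p)
  expect_true(all(read_image(p) == 255L))
  unlink(p)

  p4 <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4, 4, 4)), p4)
  expect_error(read_image(p4), "format error.*4")
  unlink(p4)
  pg <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), pg)
  expect_error(read_image(pg), "greyscale")
  unlink(pg)
  expect_error(read_image(tempfile(fileext = ".png")), "no such file")
})

test_that("tiled references use a most-square row-major grid with white padding", {
  crop <- function(v) rgb_image(array(as.integer(v), c(4, 4, 3)))
  tiled <- build_tiled_reference(list(crop(10), crop(20), crop(30)), 4)
  expect_identical(dim(tiled$image), c(8L, 8L, 3L))
  expect_equal(tiled$n_tiles, 3)
  # layout enumerated by hand: tiles fill (1,1), (1,5), (5,1); (5,5) is white
  expect_identical(tiled$tile_origins,
                   matrix(c(1L, 1L, 1L, 5L, 5L, 1L), ncol = 2, byrow = TRUE,
                          dimnames = list(NULL, c("row", "col"))))
  expect_true(all(unclass(tiled$image)[1:4, 1:4, ] == 10L))
  expect_true(all(unclass(tiled$image)[1:4, 5:8, ] == 20L))
  expect_true(all(unclass(tiled$image)[5:8, 1:4, ] == 30L))
  expect_true(all(unclass(tiled$image)[5:8, 5:8, ] == 255L))

  single <- build_tiled_reference(list(crop(7)), 4)
  expect_identical(unclass(single$image)[, , ], unclass(crop(7))[, , ])

  expect_error(build_tiled_reference(list(crop(1), rgb_image(array(0L, c(3, 3, 3)))), 4),
               "dimension error")

  # persistence round trip
  p <- tempfile(fileext = ".tiff")
  write_tiled_reference(tiled, p)
  back <- read_tiled_reference(p)
  expect_identical(unclass(back$image)[, , ], unclass(tiled$image)[, , ])
  expect_identical(back$tile_origins, tiled$tile_origins)
  unlink(c(p, paste0(p, ".json")))
})

test_that("regular pixel sampling is deterministic with the promised counts", {
  set.seed(2)
  img <- rgb_image(array(sample(0:255, 10 * 10 * 3, TRUE), c(10, 10, 3)))
  s <- sample_pixels(img, 0.25)
  expect_equal(nrow(s), 25)  # stride-2 grid on 10 x 10
  expect_identical(s, sample_pixels(img, 0.25))
  # stride-2 positions: first sampled pixel is (1,1), second is (1,3)
  expect_equal(s[1, ], unclass(img)[1, 1, ])
  expect_equal(s[2, ], unclass(img)[1, 3, ])

  all_px <- sample_pixels(img, 1)
  expect_equal(nrow(all_px), 100)
  # raster order: first 10 rows of the sample are image row 1
  expect_equal(all_px[1:10, ], unclass(img)[1, , ])

  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  sm <- sample_pixels(img, 0.5, mask = mask)
  expect_equal(nrow(sm), 25)  # floor(50 * 0.5)
  expect_error(sample_pixels(img, 0.5, mask = matrix(FALSE, 10, 10)),
               "no pixels to sample")

  # disjoint hold-out phases
  i0 <- ihcnorm:::sample_pixel_indices(10, 10, 0.25, offset = 0L)
  i1 <- ihcnorm:::sample_pixel_indices(10, 10, 0.25, offset = 1L)
  expect_equal(nrow(merge(as.data.frame(i0), as.data.frame(i1))), 0)
})
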