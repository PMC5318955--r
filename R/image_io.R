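# Raster image input/output, tiled reference assembly, and regular pixel
# sampling.  Images are exchanged as 8-bit sRGB arrays; all physics happens
# after linearisation (see sda.R).

#' 8-bit sRGB image container
#'
#' Wraps an `H x W x 3` integer array of 8-bit sRGB intensities.  White
#' (255, 255, 255) is expected to correspond to the glass-slide background
#' of a brightfield scan.
#'
#' @param pixels numeric or integer array of dimension `H x W x 3`, values
#'   in `[0, 255]`.
#' @param pixel_size_um optional scalar, micrometres per pixel.
#' @return an object of class `rgb_image` (an integer array with attributes).
#' @export
rgb_image <- function(pixels, pixel_size_um = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array, got shape [",
         paste(d %||% length(pixels), collapse = " x "), "]")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, pixel_size_um = pixel_size_um, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, 3 channels, 8-bit sRGB\n", d[1], d[2]))
  invisible(x)
}

#' Read an 8-bit RGB raster image
#'
#' Reads a PNG or TIFF file into an [rgb_image()].  Only 3-channel 8-bit
#' rasters are accepted; greyscale or alpha-carrying files are rejected so
#' that unintended inputs fail loudly rather than being silently coerced.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)"))
  d <- dim(raw)
  if (length(d) == 2L)
    stop("format error: greyscale image (shape ", d[1], " x ", d[2],
         "), expected 3 channels")
  if (d[3] != 3L)
    stop("format error: image has ", d[3],
         " channels (shape ", paste(d, collapse = " x "),
         "), expected exactly 3 (no alpha)")
  rgb_image(round(raw * 255))
}

#' Write an 8-bit RGB image to PNG or TIFF
#'
#' The inverse of [read_image()]; the round trip is bit-exact.
#'
#' @param image an [rgb_image()].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Assemble a tiled reference image from core crops
#'
#' Arranges equally sized square crops (one per tissue-microarray core) into
#' a single mosaic, row-major on the most-square grid (`ceiling(sqrt(n))`
#' columns); unused grid cells are filled with background white.  Downstream
#' steps only use the pixel *population* of the mosaic, so the layout is
#' immaterial beyond bookkeeping.
#'
#' @param crops list of [rgb_image()]s, each `tile_px x tile_px x 3`.
#' @param tile_px side length of each crop in pixels.
#' @return an object of class `tiled_reference`: list with `image`
#'   ([rgb_image()]), `tile_px`, `n_tiles` and `tile_origins` (an
#'   `n_tiles x 2` matrix of 1-based (row, col) upper-left placement
#'   positions in the mosaic).
#' @export
build_tiled_reference <- function(crops, tile_px) {
  if (length(crops) == 0L) stop("need at least one crop")
  tile_px <- as.integer(tile_px)
  for (i in seq_along(crops)) {
    d <- dim(crops[[i]])
    if (!identical(as.integer(d), c(as.integer(tile_px), as.integer(tile_px), 3L)))
      stop("dimension error: crop ", i, " has shape [",
           paste(d, collapse = " x "), "], expected ",
           tile_px, " x ", tile_px, " x 3")
  }
  n <- length(crops)
  ncol_grid <- as.integer(ceiling(sqrt(n)))
  nrow_grid <- as.integer(ceiling(n / ncol_grid))
  canvas <- array(255L, dim = c(nrow_grid * tile_px, ncol_grid * tile_px, 3L))
  origins <- matrix(0L, nrow = n, ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    gr <- (i - 1L) %/% ncol_grid
    gc <- (i - 1L) %% ncol_grid
    r0 <- gr * tile_px + 1L
    c0 <- gc * tile_px + 1L
    canvas[r0:(r0 + tile_px - 1L), c0:(c0 + tile_px - 1L), ] <- unclass(crops[[i]])
    origins[i, ] <- c(r0, c0)
  }
  structure(list(image = rgb_image(canvas), tile_px = as.integer(tile_px),
                 n_tiles = n, tile_origins = origins),
            class = "tiled_reference")
}

#' @export
print.tiled_reference <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<tiled_reference> %d tiles of %d px, mosaic %d x %d px\n",
              x$n_tiles, x$tile_px, d[1], d[2]))
  invisible(x)
}

# linear (1-based) pixel indices of a deterministic regular sample.
# Without a mask: a fixed-stride grid (stride = floor(1/sqrt(fraction)) per
# axis) scanned in raster (row-major) order, truncated to
# floor(H*W*fraction) pixels.  With a mask: every floor(1/fraction)-th
# masked-in pixel in raster order, truncated to floor(n_masked*fraction).
# `offset` shifts the sampling phase; disjoint offsets give disjoint
# training/hold-out samples without randomness.
sample_pixel_indices <- function(h, w, fraction, mask = NULL, offset = 0L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(mask)) {
    if (fraction == 1 && offset == 0L) {
      idx <- cbind(rep(seq_len(h), each = w), rep(seq_len(w), times = h))
    } else {
      s <- max(1L, floor(1 / sqrt(fraction)))
      rows <- seq.int(1L + offset %% s, h, by = s)
      cols <- seq.int(1L + offset %% s, w, by = s)
      if (length(rows) == 0L || length(cols) == 0L)
        stop("no pixels to sample")
      idx <- cbind(rep(rows, each = length(cols)), rep(cols, times = length(rows)))
    }
    n_target <- max(1L, floor(h * w * fraction))
  } else {
    stopifnot(identical(dim(mask), c(h, w)))
    keep <- which(t(mask))          # raster (row-major) order
    if (length(keep) == 0L) stop("no pixels to sample")
    s <- max(1L, floor(1 / fraction))
    keep <- keep[seq.int(1L + offset %% s, length(keep), by = s)]
    rc <- cbind((keep - 1L) %/% w + 1L, (keep - 1L) %% w + 1L)
    idx <- rc
    n_target <- max(1L, floor(sum(mask) * fraction))
  }
  if (nrow(idx) > n_target) idx <- idx[seq_len(n_target), , drop = FALSE]
  idx
}

#' Regularly sample pixels from an image
#'
#' Deterministic fixed-stride ("regular") sampling of pixel triples, used to
#' build the small training sets for colour-vector extraction (typically
#' 0.1\% of a ~25-million-pixel tiled reference, i.e. ~25,000 pixels) and
#' disjoint hold-out sets for quality control.  No random numbers are used:
#' identical inputs always yield identical samples.
#'
#' @param image an [rgb_image()] or `sda_image` (see [rgb_to_sda()]).
#' @param fraction sampling fraction in `(0, 1]`.
#' @param mask optional logical `H x W` matrix restricting the sample.
#' @param offset integer phase shift; different offsets give disjoint
#'   regular samples (training vs hold-out).
#' @return an `n x 3` matrix of pixel triples (raw 8-bit values for
#'   `rgb_image`, staining-darkness values for `sda_image`),
#'   `n = floor(n_pixels * fraction)`.
#' @export
sample_pixels <- function(image, fraction, mask = NULL, offset = 0L) {
  d <- dim(image)
  idx <- sample_pixel_indices(d[1], d[2], fraction, mask, as.integer(offset))
  arr <- unclass(image)
  cbind(arr[cbind(idx, 1L)], arr[cbind(idx, 2L)], arr[cbind(idx, 3L)])
}

#' Persist / load a tiled reference
#'
#' Writes the mosaic as a single 8-bit TIFF with a JSON sidecar
#' (`<path>.json`) holding the tile geometry.
#'
#' @param x a `tiled_reference`.
#' @param path TIFF path.
#' @return `path` (write) or a `tiled_reference` (read).
#' @export
write_tiled_reference <- function(x, path) {
  stopifnot(inherits(x, "tiled_reference"))
  write_image(x$image, path)
  meta <- list(tile_px = x$tile_px, n_tiles = x$n_tiles,
               tile_origins = unname(x$tile_origins))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tiled_reference
#' @export
read_tiled_reference <- function(path) {
  img <- read_image(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  origins <- matrix(as.integer(meta$tile_origins), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  structure(list(image = img, tile_px = as.integer(meta$tile_px),
                 n_tiles = as.integer(meta$n_tiles), tile_origins = origins),
            class = "tiled_reference")
}
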