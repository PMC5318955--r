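# Staining darkness (SDA) transform: an optical-density-like quantity
# SDA_c = max(0, -log10(min(I_c, I0_c) / I0_c)) computed on linearised RGB
# intensities, where I0 is the per-channel glass-background intensity.
# The clamp makes the transform total (pixels lighter than glass map to 0),
# and no Beer-Lambert claim is attached to DAB: SDA is a monotone darkness
# scale, which is all that colour deconvolution and quantification need.

# IEC 61966-2-1 sRGB transfer function, on [0, 1]
srgb_decode <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
srgb_encode <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Background (glass) intensity
#'
#' Container for the per-channel background intensity `I0` on the linearised
#' sRGB scale in `(0, 1]`.
#'
#' @param I0 numeric length-3 vector, strictly positive.
#' @return object of class `sda_background`.
#' @export
sda_background <- function(I0) {
  stopifnot(length(I0) == 3L, all(is.finite(I0)), all(I0 > 0), all(I0 <= 1))
  structure(list(I0 = as.numeric(I0), colorspace = "linear-sRGB"),
            class = "sda_background")
}

#' @export
print.sda_background <- function(x, ...) {
  cat("<sda_background> I0 (linear sRGB):",
      paste(sprintf("%.4f", x$I0), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the glass-background intensity and a tissue mask
#'
#' Estimates `I0` from the glass region of a brightfield image: (1) a
#' greyscale image is formed as the per-pixel minimum over the linearised
#' RGB channels; (2) Otsu's threshold on this greyscale separates (darker)
#' tissue from glass; (3) the tissue region is morphologically dilated
#' (disc structuring element) to exclude tissue-halo pixels; (4) `I0` in
#' each channel is the *mode* of the raw 8-bit intensity histogram outside
#' the dilated mask, then linearised.  Using the mode rather than the
#' maximum makes the estimate robust to isolated glass artefacts.
#'
#' A uniform (blank) image is degenerate for Otsu; in that case the global
#' per-channel mode is returned with an empty tissue mask and a warning, so
#' blank control tiles do not abort a pipeline.
#'
#' @param image an [rgb_image()].
#' @param dilate_radius disc radius in pixels for the tissue dilation
#'   (default 5, appropriate at ~0.45 um/px).
#' @return list with `background` ([sda_background()]) and `tissue_mask`
#'   (logical `H x W` matrix).
#' @export
estimate_background <- function(image, dilate_radius = 5L) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image)
  lin <- srgb_decode(arr / 255)
  grey <- pmin(lin[, , 1], pmin(lin[, , 2], lin[, , 3]))
  channel_mode <- function(raw_vals) {
    h <- tabulate(raw_vals + 1L, nbins = 256L)
    mode_raw <- which.max(h) - 1L
    srgb_decode(max(mode_raw, 1L) / 255)
  }
  if (diff(range(grey)) < 1e-10) {
    warning("uniform image: no tissue detected; using global mode as background")
    I0 <- vapply(1:3, function(ch) channel_mode(as.vector(arr[, , ch])), 0)
    return(list(background = sda_background(I0),
                tissue_mask = matrix(FALSE, dim(arr)[1], dim(arr)[2])))
  }
  thr <- EBImage::otsu(EBImage::Image(grey), range = range(grey), levels = 256L)
  tissue <- grey < thr
  if (!any(tissue)) {
    warning("no tissue detected by Otsu threshold; using global mode as background")
    I0 <- vapply(1:3, function(ch) channel_mode(as.vector(arr[, , ch])), 0)
    return(list(background = sda_background(I0),
                tissue_mask = matrix(FALSE, dim(arr)[1], dim(arr)[2])))
  }
  if (dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, shape = "disc")
    tissue <- EBImage::dilate(EBImage::Image(tissue * 1), brush) > 0.5
  }
  tissue <- matrix(as.logical(tissue), nrow = dim(arr)[1])
  if (all(tissue)) stop("no background region: tissue mask covers the whole image")
  bg_px <- which(!tissue)
  I0 <- vapply(1:3, function(ch) {
    channel_mode(as.vector(arr[, , ch])[bg_px])
  }, 0)
  list(background = sda_background(I0), tissue_mask = tissue)
}

#' RGB to staining darkness
#'
#' Transforms 8-bit sRGB intensities to staining darkness per channel:
#' `SDA_c = -log10(min(I_c, I0_c) / I0_c)` on linearised intensities, which
#' is zero for pixels at (or lighter than) the glass background and grows
#' with darkness.  Zero raw intensities are floored at one grey level
#' before the logarithm, capping SDA at about 2.4 relative to white.
#'
#' @param image an [rgb_image()], or an `n x 3` matrix of raw 8-bit triples.
#' @param background an [sda_background()].
#' @return an `sda_image` (`H x W x 3` double array, attribute `background`)
#'   or an `n x 3` matrix when `image` is a matrix.
#' @export
rgb_to_sda <- function(image, background) {
  stopifnot(inherits(background, "sda_background"))
  I0 <- background$I0
  floor_lin <- srgb_decode(1 / 255)
  transform <- function(raw, i0) {
    lin <- pmax(srgb_decode(raw / 255), floor_lin)
    -log10(pmin(lin, i0) / i0)
  }
  if (is.matrix(image)) {
    out <- vapply(1:3, function(ch) transform(image[, ch], I0[ch]),
                  numeric(nrow(image)))
    if (nrow(image) == 1L) out <- matrix(out, nrow = 1L)
    return(out)
  }
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image)
  out <- array(0, dim = dim(arr))
  for (ch in 1:3) out[, , ch] <- transform(arr[, , ch], I0[ch])
  structure(out, background = background, class = "sda_image")
}

#' Staining darkness back to RGB
#'
#' Inverse of [rgb_to_sda()]: `I_c = I0_c * 10^(-SDA_c)`, re-encoded to
#' 8-bit sRGB with rounding.  The round trip through [rgb_to_sda()] is
#' within one grey level for pixels at most as bright as the background.
#'
#' @param sda an `sda_image` or `n x 3` SDA matrix.
#' @param background an [sda_background()]; defaults to the one attached to
#'   `sda`.
#' @return an [rgb_image()] or `n x 3` matrix of raw 8-bit values.
#' @export
sda_to_rgb <- function(sda, background = attr(sda, "background")) {
  stopifnot(inherits(background, "sda_background"))
  I0 <- background$I0
  encode <- function(vals, i0) {
    as.integer(pmin(pmax(round(255 * srgb_encode(i0 * 10^(-vals))), 0), 255))
  }
  if (is.matrix(sda)) {
    out <- vapply(1:3, function(ch) encode(sda[, ch], I0[ch]), integer(nrow(sda)))
    if (nrow(sda) == 1L) out <- matrix(out, nrow = 1L)
    return(out)
  }
  arr <- unclass(sda)
  out <- array(0L, dim = dim(arr))
  for (ch in 1:3) out[, , ch] <- encode(arr[, , ch], I0[ch])
  rgb_image(out)
}

#' Persist an SDA image or background
#'
#' The SDA image is written as a 32-bit float multi-channel TIFF; the
#' background as JSON.
#'
#' @param sda an `sda_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @details `write_sda_image` stores values divided by a recorded scale (the
#'   TIFF float range is `[0, 1]`); the scale and background go to a
#'   `<path>.json` sidecar and `read_sda_image` restores both.
#' @export
write_sda_image <- function(sda, path) {
  arr <- unclass(sda)
  scale <- max(1, max(arr))
  attributes(arr) <- list(dim = dim(arr))
  tiff::writeTIFF(arr / scale, path, bits.per.sample = 32L)
  bg <- attr(sda, "background")
  jsonlite::write_json(list(scale = scale, I0 = bg$I0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sda_image
#' @export
read_sda_image <- function(path) {
  arr <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(arr * meta$scale, background = sda_background(meta$I0),
            class = "sda_image")
}

#' @rdname write_sda_image
#' @param background an [sda_background()].
#' @export
write_background <- function(background, path) {
  jsonlite::write_json(list(I0 = background$I0, colorspace = background$colorspace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sda_image
#' @export
read_background <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sda_background(obj$I0)
}
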