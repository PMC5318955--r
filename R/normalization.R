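# Colour matching and distribution fitting.  Deconvolution expresses each
# pixel's SDA vector as coefficients on the batch's own HEM/DAB axes
# (colour matching aligns batches by doing this per batch); the optional
# per-channel fits then map one batch's deconvoluted value distribution
# onto the target batch's.  Fits are always applied in deconvoluted space,
# never on raw SDA.

#' Deconvolve an SDA image into stain coefficients
#'
#' Solves `M %*% coefficients = sda` per pixel, where `M = [a b c]` is the
#' stain basis.  The third (residual) coefficient is retained for quality
#' control; for a well-extracted basis it is near zero.  Negative HEM/DAB
#' coefficients indicate a negligible contribution of that stain and can be
#' clipped to zero (`clip = TRUE`) for quantification; QC paths keep them
#' as diagnostics.
#'
#' @param sda an `sda_image` (see [rgb_to_sda()]) or `n x 3` SDA matrix.
#' @param basis a [stain_basis()].
#' @param clip clip negative HEM/DAB coefficients to zero?
#' @return for an image, an object of class `deconvolved_image`: list with
#'   `hem`, `dab`, `residual` (`H x W` matrices), `basis`, `clipped`; for a
#'   matrix input, an `n x 3` coefficient matrix (columns hem, dab,
#'   residual).
#' @export
deconvolve <- function(sda, basis, clip = FALSE) {
  stopifnot(inherits(basis, "stain_basis"))
  if (abs(det(basis$M)) < 1e-12) stop("singular deconvolution matrix")
  Minv <- solve(basis$M)
  if (is.matrix(sda) && length(dim(sda)) == 2L) {
    co <- t(Minv %*% t(sda))
    colnames(co) <- c("hem", "dab", "residual")
    if (clip) { co[, 1] <- pmax(co[, 1], 0); co[, 2] <- pmax(co[, 2], 0) }
    return(co)
  }
  arr <- unclass(sda)
  d <- dim(arr)
  flat <- matrix(arr, ncol = 3L)
  co <- t(Minv %*% t(flat))
  hem <- matrix(co[, 1], d[1], d[2])
  dab <- matrix(co[, 2], d[1], d[2])
  res <- matrix(co[, 3], d[1], d[2])
  if (clip) { hem <- pmax(hem, 0); dab <- pmax(dab, 0) }
  structure(list(hem = hem, dab = dab, residual = res,
                 basis = basis, clipped = clip),
            class = "deconvolved_image")
}

#' @export
print.deconvolved_image <- function(x, ...) {
  cat(sprintf("<deconvolved_image> %d x %d px (basis: %s, %s)\n",
              nrow(x$hem), ncol(x$hem), x$basis$method_tag,
              if (x$clipped) "clipped" else "unclipped"))
  invisible(x)
}

# recompose coefficient channels into an SDA image using the given basis;
# the residual channel is zeroed (it is a QC axis, not a stain).
recompose_sda <- function(hem, dab, basis, background) {
  d <- dim(hem)
  flat <- cbind(as.vector(hem), as.vector(dab))
  sda <- flat %*% rbind(basis$a, basis$b)
  structure(array(pmax(sda, 0), dim = c(d, 3L)),
            background = background, class = "sda_image")
}

new_channel_fit <- function(method, params, channel = NA_character_,
                            source_batch_id = NA_character_,
                            target_batch_id = NA_character_) {
  structure(list(method = method, channel = channel, params = params,
                 source_batch_id = source_batch_id,
                 target_batch_id = target_batch_id),
            class = "channel_fit")
}

#' @export
print.channel_fit <- function(x, ...) {
  cat(sprintf("<channel_fit> method = %s, channel = %s\n", x$method, x$channel))
  invisible(x)
}

# matched quantile pairs at (i - 0.5)/n probabilities, duplicates on the
# source side collapsed (mean target per distinct source quantile)
matched_quantile_pairs <- function(source, target, n_quantiles = 1000L) {
  qs <- sample_quantiles(source, n_quantiles)
  qt <- sample_quantiles(target, n_quantiles)
  agg <- tapply(qt, qs, mean)
  x <- as.numeric(names(agg))
  y <- cummax(as.numeric(agg))   # enforce monotonicity through ties
  list(x = x, y = y)
}

#' Percentile-99 rescaling fit
#'
#' The classic robust-maximum rescaling: maps `x` to
#' `x * P99(target) / P99(source)`.  A pure gain correction — it can only
#' stretch or shrink the distribution, so on a nonlinearly deformed batch
#' it can *worsen* the quantile agreement obtained by colour matching; it
#' is provided because it is in common use, not because it is recommended.
#'
#' @param source,target nonnegative numeric samples of deconvoluted SDA
#'   values from the batch to normalise and the target batch.
#' @return a `channel_fit` (method `p99_rescale`).
#' @export
fit_p99 <- function(source, target) {
  stopifnot(length(source) > 0, length(target) > 0)
  p99s <- stats::quantile(source, 0.99, type = 5, names = FALSE)
  p99t <- stats::quantile(target, 0.99, type = 5, names = FALSE)
  if (p99s <= 0) stop("degenerate source distribution: P99 is zero")
  new_channel_fit("p99_rescale", list(scale = p99t / p99s))
}

#' Empirical quantile-matching fit
#'
#' Full empirical-CDF matching: maps `x` to `Q_target(F_source(x))` through
#' a 1000-point monotone lookup table with linear interpolation, extended
#' linearly beyond the observed range (and floored at zero).  Matching the
#' CDFs directly, it never increases the KS distance between the mapped
#' source and the target.
#'
#' @inheritParams fit_p99
#' @param n_quantiles lookup-table resolution.
#' @return a `channel_fit` (method `quantile_match`).
#' @export
fit_quantile_match <- function(source, target, n_quantiles = 1000L) {
  stopifnot(length(source) > 0, length(target) > 0)
  p <- matched_quantile_pairs(source, target, n_quantiles)
  new_channel_fit("quantile_match", list(x = p$x, y = p$y))
}

#' Linear quantile-regression fit
#'
#' Least-squares line through the matched quantile pairs
#' (source-quantile, target-quantile); maps `x` to
#' `max(0, slope * x + intercept)`.  Both quantile sequences are
#' non-decreasing, so the slope is nonnegative and the mapping monotone.
#'
#' @inheritParams fit_quantile_match
#' @return a `channel_fit` (method `linear`).
#' @export
fit_linear <- function(source, target, n_quantiles = 1000L) {
  stopifnot(length(source) > 0, length(target) > 0)
  qs <- sample_quantiles(source, n_quantiles)
  qt <- sample_quantiles(target, n_quantiles)
  if (stats::var(qs) < .Machine$double.eps)
    stop("degenerate source distribution: zero variance")
  co <- stats::coef(stats::lm(qt ~ qs))
  new_channel_fit("linear", list(intercept = unname(co[1]),
                                 slope = unname(co[2])))
}

#' Penalised B-spline quantile-regression fit
#'
#' Regresses the target quantiles on the source quantiles with a penalised
#' B-spline basis (`n_splines` basis functions, P-spline penalty, smoothing
#' chosen by generalised cross-validation), then projects the fitted curve
#' onto the monotone non-decreasing cone (isotonic regression) so the
#' mapping is a valid intensity transform.  Evaluation interpolates the
#' fitted curve linearly and extrapolates flat beyond the training range,
#' which caps the transform on rare very dark pixels.  This is the method
#' of choice for *nonlinear* intensity deformations (e.g. a reagent-lot
#' change) that colour matching alone cannot correct.
#'
#' @inheritParams fit_quantile_match
#' @param n_splines number of B-spline basis functions (default 100).
#' @return a `channel_fit` (method `bspline`).
#' @export
fit_bspline <- function(source, target, n_splines = 100L, n_quantiles = 1000L) {
  stopifnot(length(source) > 0, length(target) > 0)
  qs <- sample_quantiles(source, n_quantiles)
  qt <- sample_quantiles(target, n_quantiles)
  if (stats::var(qs) < .Machine$double.eps)
    stop("degenerate source distribution: zero variance")
  if (n_quantiles < n_splines / 2)
    stop("need at least n_splines/2 matched quantile pairs")
  k <- min(n_splines, max(4L, length(unique(qs)) - 1L))
  df <- data.frame(qs = qs, qt = qt)
  g <- suppressWarnings(
    mgcv::gam(qt ~ s(qs, k = k, bs = "ps"), data = df, method = "GCV.Cp"))
  fitted_vals <- as.numeric(stats::fitted(g))
  o <- order(qs)
  iso <- stats::isoreg(seq_along(o), fitted_vals[o])$yf
  x <- qs[o]
  keep <- !duplicated(x)
  new_channel_fit("bspline",
                  list(x = x[keep], y = pmax(iso[keep], 0),
                       n_splines = as.integer(n_splines)))
}

#' Evaluate a channel fit
#'
#' Applies the monotone mapping defined by a `channel_fit` to new
#' deconvoluted SDA values.
#'
#' @param object a `channel_fit`.
#' @param newdata numeric vector (or matrix) of values to map.
#' @param ... unused.
#' @return mapped values, same shape as `newdata`; always nonnegative for
#'   nonnegative input.
#' @export
predict.channel_fit <- function(object, newdata, ...) {
  x <- newdata
  dims <- dim(x)
  v <- as.numeric(x)
  out <- switch(object$method,
    none = v,
    p99_rescale = object$params$scale * v,
    linear = pmax(object$params$intercept + object$params$slope * v, 0),
    quantile_match = eval_lookup(v, object$params$x, object$params$y,
                                 extrapolate = "linear"),
    bspline = eval_lookup(v, object$params$x, object$params$y,
                          extrapolate = "flat"),
    stop("unknown fit method: ", object$method))
  dim(out) <- dims
  out
}

# monotone lookup-table evaluation with linear interpolation; beyond the
# table range either extend linearly using the end-segment slopes or hold
# flat.  Output floored at 0.
eval_lookup <- function(v, x, y, extrapolate = c("linear", "flat")) {
  extrapolate <- match.arg(extrapolate)
  if (length(x) == 1L) return(pmax(rep(y, length(v)), 0))
  out <- stats::approx(x, y, xout = v, rule = 2)$y
  if (extrapolate == "linear") {
    lo <- v < x[1]
    hi <- v > x[length(x)]
    if (any(lo)) {
      s <- (y[2] - y[1]) / (x[2] - x[1])
      out[lo] <- y[1] + s * (v[lo] - x[1])
    }
    if (any(hi)) {
      n <- length(x)
      s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      out[hi] <- y[n] + s * (v[hi] - x[n])
    }
  }
  pmax(out, 0)
}

#' Normalise an image to a target batch's colour frame
#'
#' The full per-image normalisation: (1) SDA transform with the image's own
#' batch background; (2) deconvolution with the batch's own stain basis
#' (colour matching); (3) optional per-channel distribution fit mapping the
#' batch's deconvoluted values onto the target's; (4) recomposition of the
#' normalised SDA vector with the *target* basis (so all normalised images
#' share one colour frame; the residual channel is zeroed) and conversion
#' back to 8-bit RGB with the target background.
#'
#' @param image an [rgb_image()].
#' @param basis_k [stain_basis()] extracted from the image's own batch.
#' @param fits optional named list with elements `hem` and `dab`, each a
#'   `channel_fit` mapping batch values to the target.
#' @param background [sda_background()] of the image's own batch.
#' @param target_basis,target_background the target batch's basis and
#'   background; default to the source's (pure colour matching into the
#'   batch's own frame).
#' @param clip clip negative coefficients before recomposition (default
#'   TRUE; use FALSE on QC paths that need the negatives).
#' @return list with `deconvolved` (a `deconvolved_image`, after fitting)
#'   and `normalised` (an [rgb_image()]).
#' @export
apply_normalization <- function(image, basis_k, fits = NULL, background,
                                target_basis = basis_k,
                                target_background = background,
                                clip = TRUE) {
  stopifnot(inherits(image, "rgb_image"))
  sda <- rgb_to_sda(image, background)
  dec <- deconvolve(sda, basis_k, clip = clip)
  if (!is.null(fits)) {
    if (!is.null(fits$hem)) dec$hem <- predict(fits$hem, dec$hem)
    if (!is.null(fits$dab)) dec$dab <- predict(fits$dab, dec$dab)
  }
  nsda <- recompose_sda(dec$hem, dec$dab, target_basis, target_background)
  list(deconvolved = dec, normalised = sda_to_rgb(nsda, target_background))
}

#' Serialise channel fits to JSON
#'
#' @param fits named list of `channel_fit`s (e.g. `hem`, `dab`).
#' @param path output JSON path.
#' @return `path` (write) or the fit list (read).
#' @export
write_channel_fits <- function(fits, path) {
  payload <- lapply(fits, function(f)
    list(method = f$method, channel = f$channel, params = f$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_fits
#' @export
read_channel_fits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(f)
    new_channel_fit(f$method, as.list(f$params), channel = f$channel %||% NA_character_))
}
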