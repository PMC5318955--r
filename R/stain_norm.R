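# The central estimator: fit an inter-batch normalisation transform from a
# source batch's reference image to a target batch's, and apply it to new
# images of the source batch.

#' Fit an inter-batch stain-normalisation transform
#'
#' Estimates everything needed to normalise images of one IHC staining
#' batch into the colour frame of a target batch: per-batch glass
#' backgrounds, per-batch HEM/DAB stain bases extracted blindly from a
#' regular training sample of each reference image (colour matching), and
#' optionally a monotone per-channel distribution fit mapping the source
#' batch's deconvoluted SDA values onto the target's.  Quality control is
#' computed on a hold-out pixel sample disjoint from the training sample,
#' at three stages: `before_matching` (the target's basis imposed on the
#' source batch), `after_matching` (each batch deconvolved with its own
#' basis) and, when a fit is requested, `after_fitting`.
#'
#' @param source,target reference images for the batch to normalise and
#'   the target batch: [rgb_image()], `tiled_reference`, or a file path.
#' @param method stain-extraction method (see [extract_stains()]).
#' @param fit distribution-fitting method: `"none"` (default; colour
#'   matching only), `"p99"`, `"quantile"`, `"linear"` or `"bspline"`.
#' @param config an [extraction_config()].
#' @param n_quantiles Q-Q resolution for QC and quantile-based fits.
#' @param n_splines B-spline basis size when `fit = "bspline"`.
#' @param dilate_radius tissue-mask dilation radius for background
#'   estimation.
#' @return an object of class `stain_norm`: list with `basis` (source and
#'   target [stain_basis()]), `background` (source and target
#'   [sda_background()]), `fits` (NULL or per-channel `channel_fit`s),
#'   `qc` (list of `qc_report`s), `plane_quality` (source/target residual
#'   ratios), `method`, `fit_method`, `config`, `call`.  Methods:
#'   [predict.stain_norm()], `print`, `summary`, `coef`, `plot`,
#'   `residuals`.
#' @examples
#' spec <- synthetic_spec(n_cores = 9, tile_px = 60, seed = 7)
#' ref <- generate_reference(spec, pixel_truth = FALSE)
#' batch2 <- perturb_batch(spec, batch_perturbation(rotation_deg_hem = 8,
#'                                                  rotation_deg_dab = -8),
#'                         pixel_truth = FALSE)
#' fit <- stain_norm(batch2$reference, ref$reference,
#'                   config = extraction_config(sample_fraction = 0.05))
#' summary(fit)
#' norm_img <- predict(fit, batch2$reference$image)
#' @export
stain_norm <- function(source, target,
                       method = c("macenko", "li-init", "li-init-nmf",
                                  "snmf", "li-init-snmf"),
                       fit = c("none", "p99", "quantile", "linear", "bspline"),
                       config = extraction_config(),
                       n_quantiles = 1000L,
                       n_splines = 100L,
                       dilate_radius = 5L) {
  method <- match.arg(method)
  fit <- match.arg(fit)
  cl <- match.call()
  src_img <- resolve_image(source)
  tgt_img <- resolve_image(target)

  bg_s <- estimate_background(src_img, dilate_radius)$background
  bg_t <- estimate_background(tgt_img, dilate_radius)$background

  # disjoint regular samples: training at phase 0, hold-out at half-stride
  stride <- max(1L, floor(1 / sqrt(config$sample_fraction)))
  hold_off <- max(1L, stride %/% 2L)
  train_s <- sample_pixels(src_img, config$sample_fraction)
  train_t <- sample_pixels(tgt_img, config$sample_fraction)
  hold_s <- sample_pixels(src_img, config$sample_fraction, offset = hold_off)
  hold_t <- sample_pixels(tgt_img, config$sample_fraction, offset = hold_off)

  basis_s <- extract_stains_pixels(train_s, bg_s, method, config)
  basis_t <- extract_stains_pixels(train_t, bg_t, method, config)

  thr <- config$background_sda_threshold
  sda_nb <- function(px, bg) {
    s <- rgb_to_sda(px, bg)
    drop_background_pixels(s, thr)
  }
  train_s_nb <- sda_nb(train_s, bg_s)
  train_t_nb <- sda_nb(train_t, bg_t)
  hold_s_nb <- sda_nb(hold_s, bg_s)
  hold_t_nb <- sda_nb(hold_t, bg_t)

  co_tgt <- deconvolve(hold_t_nb, basis_t)
  co_before <- deconvolve(hold_s_nb, basis_t)
  co_after <- deconvolve(hold_s_nb, basis_s)

  fits <- NULL
  if (fit != "none") {
    tr_s <- deconvolve(train_s_nb, basis_s, clip = TRUE)
    tr_t <- deconvolve(train_t_nb, basis_t, clip = TRUE)
    fit_fun <- switch(fit,
      p99 = fit_p99,
      quantile = function(s, t) fit_quantile_match(s, t, n_quantiles),
      linear = function(s, t) fit_linear(s, t, n_quantiles),
      bspline = function(s, t) fit_bspline(s, t, n_splines, n_quantiles))
    fits <- list(hem = fit_fun(tr_s[, "hem"], tr_t[, "hem"]),
                 dab = fit_fun(tr_s[, "dab"], tr_t[, "dab"]))
    fits$hem$channel <- "hem"
    fits$dab$channel <- "dab"
  }

  qc <- list()
  for (ch in c("hem", "dab")) {
    qc[[paste0("before_", ch)]] <-
      qc_report(co_before[, ch], co_tgt[, ch], n_quantiles,
                stage = "before_matching", channel = ch)
    qc[[paste0("after_", ch)]] <-
      qc_report(co_after[, ch], co_tgt[, ch], n_quantiles,
                stage = "after_matching", channel = ch)
    if (!is.null(fits)) {
      mapped <- predict(fits[[ch]], pmax(co_after[, ch], 0))
      qc[[paste0("fitted_", ch)]] <-
        qc_report(mapped, pmax(co_tgt[, ch], 0), n_quantiles,
                  stage = "after_fitting", channel = ch)
    }
  }

  structure(list(
    basis = list(source = basis_s, target = basis_t),
    background = list(source = bg_s, target = bg_t),
    fits = fits,
    qc = qc,
    plane_quality = c(source = plane_quality(hold_s_nb, basis_s, thr),
                      target = plane_quality(hold_t_nb, basis_t, thr)),
    residual_coef = co_after[, "residual"],
    method = method, fit_method = fit,
    config = config, n_quantiles = as.integer(n_quantiles),
    call = cl), class = "stain_norm")
}

resolve_image <- function(x) {
  if (is.character(x)) x <- read_image(x)
  if (inherits(x, "tiled_reference")) x <- x$image
  stopifnot(inherits(x, "rgb_image"))
  x
}

#' Normalise new images with a fitted transform
#'
#' Applies a fitted [stain_norm()] transform to an image of the source
#' batch: SDA transform with the source background, deconvolution with the
#' source basis, optional per-channel fit, recomposition with the *target*
#' basis and background.
#'
#' @param object a `stain_norm` fit.
#' @param newdata an [rgb_image()], `tiled_reference`, or file path.
#' @param clip clip negative coefficients (default TRUE).
#' @param ... unused.
#' @return list with `normalised` ([rgb_image()]) and `deconvolved`
#'   (`deconvolved_image` in the matched coefficient frame).
#' @export
predict.stain_norm <- function(object, newdata, clip = TRUE, ...) {
  img <- resolve_image(newdata)
  apply_normalization(img, object$basis$source, object$fits,
                      object$background$source,
                      target_basis = object$basis$target,
                      target_background = object$background$target,
                      clip = clip)
}

#' @export
print.stain_norm <- function(x, ...) {
  cat("Inter-batch IHC stain normalisation\n")
  cat(sprintf("  extraction: %s;  distribution fit: %s\n",
              x$method, x$fit_method))
  cat(sprintf("  HEM axis (source -> target angle): %.2f deg;  DAB: %.2f deg\n",
              angle_deg(x$basis$source$a, x$basis$target$a),
              angle_deg(x$basis$source$b, x$basis$target$b)))
  after <- vapply(c("hem", "dab"), function(ch)
    x$qc[[paste0("after_", ch)]]$ks_stat, 0)
  cat(sprintf("  hold-out KS after matching: HEM %.3f, DAB %.3f\n",
              after["hem"], after["dab"]))
  invisible(x)
}

#' @export
summary.stain_norm <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$qc, as.data.frame))
  rownames(tab) <- NULL
  structure(list(fit = object, qc_table = tab), class = "summary.stain_norm")
}

#' @export
print.summary.stain_norm <- function(x, ...) {
  print(x$fit)
  cat("\nStain bases (rows HEM / DAB / residual):\n  source:\n")
  print(round(rbind(x$fit$basis$source$a, x$fit$basis$source$b,
                    x$fit$basis$source$c), 4))
  cat("  target:\n")
  print(round(rbind(x$fit$basis$target$a, x$fit$basis$target$b,
                    x$fit$basis$target$c), 4))
  cat(sprintf("\nPlane quality (residual/in-plane ratio): source %.4f, target %.4f\n",
              x$fit$plane_quality["source"], x$fit$plane_quality["target"]))
  cat("\nHold-out quality control:\n")
  print(x$qc_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.stain_norm <- function(object, ...) {
  list(source = object$basis$source$M, target = object$basis$target$M)
}

#' Q-Q diagnostic plot for a fitted normalisation
#'
#' Paired-quantile plots of the source batch's deconvoluted values against
#' the target's, per channel and stage, with the 45-degree identity line.
#' Points on the line indicate distributional equality.
#'
#' @param x a `stain_norm` fit.
#' @param channels channels to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stain_norm <- function(x, channels = c("hem", "dab"), ...) {
  stages <- c(before = "before_", after = "after_",
              fitted = if (!is.null(x$fits)) "fitted_")
  op <- graphics::par(mfrow = c(length(channels), length(stages)))
  on.exit(graphics::par(op))
  for (ch in channels) {
    for (s in seq_along(stages)) {
      rep_name <- paste0(stages[s], ch)
      qq <- x$qc[[rep_name]]$qq
      lim <- range(qq$q_source, qq$q_target)
      graphics::plot(qq$q_target, qq$q_source, pch = ".", xlim = lim,
                     ylim = lim, xlab = "target quantiles",
                     ylab = "source quantiles",
                     main = sprintf("%s, %s", ch, x$qc[[rep_name]]$stage), ...)
      graphics::abline(0, 1, col = "grey50")
    }
  }
  invisible(x)
}

#' @export
residuals.stain_norm <- function(object, ...) {
  object$residual_coef
}
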