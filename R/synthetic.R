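# Synthetic two-stain (HEM + DAB) brightfield image generator with known
# ground truth, plus batch perturbations emulating the inter-batch effects
# the normalisation corrects: colour-vector rotation (colour drift /
# yellowing), monotone nonlinear intensity deformation (reagent-lot
# change), and a global tint.  Each tissue core is a tile; pixels are
# background glass, HEM-only, DAB-only, or mixed, with gamma-distributed
# stain concentrations.  No tissue texture or nucleus morphology is
# simulated: only the colour/intensity population matters to the method.

#' Specification for a synthetic two-stain reference
#'
#' Defaults emulate a ~100-core tissue-microarray tiled reference of
#' 500 x 500 px crops (~25 million pixels) with hematoxylin and DAB axes
#' at the commonly published directions, moderately abundant DAB staining,
#' and additive SDA noise matching a
#' calibrated scanner (about 1.5 grey levels at mid intensity).
#'
#' @param v_hem,v_dab ground-truth unit SDA axes (non-collinear).
#' @param hem_conc,dab_conc concentration distributions: list with `shape`,
#'   `scale` (gamma) and `min` (offset, keeping stained pixels away from
#'   the background cut-off).
#' @param frac_background,frac_hem_only,frac_dab_only,frac_mixed expected
#'   pixel-class proportions (sum to 1).  The background fraction is
#'   realised geometrically as the contiguous glass margin around a
#'   centred circular tissue core in each tile (so it must be at least
#'   `1 - pi/4`); the tissue classes are drawn per pixel inside the disc.
#' @param core_dirichlet Dirichlet concentration controlling how much the
#'   class proportions vary from core to core (larger = more homogeneous).
#' @param noise_sd additive Gaussian SDA noise per channel on stained
#'   (tissue) pixels.
#' @param glass_noise_sd SDA noise on glass pixels; a calibrated scanner
#'   leaves the background far cleaner than the tissue signal (default
#'   0.002, well below the background cut-off).
#' @param n_cores number of cores (tiles).
#' @param tile_px tile side length in pixels.
#' @param seed integer seed; the whole generation is deterministic in it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(v_hem = c(0.650, 0.704, 0.286),
                           v_dab = c(0.268, 0.570, 0.776),
                           hem_conc = list(shape = 2, scale = 0.25, min = 0.05),
                           dab_conc = list(shape = 2, scale = 0.30, min = 0.05),
                           frac_background = 0.30,
                           frac_hem_only = 0.49,
                           frac_dab_only = 0.07,
                           frac_mixed = 0.14,
                           core_dirichlet = 60,
                           noise_sd = 0.005,
                           glass_noise_sd = 0.002,
                           n_cores = 100L,
                           tile_px = 500L,
                           seed = 1L) {
  v_hem <- unitize(v_hem); v_dab <- unitize(v_dab)
  fr <- c(frac_background, frac_hem_only, frac_dab_only, frac_mixed)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("class proportions must be nonnegative and sum to 1")
  if (angle_deg(v_hem, v_dab) < 15)
    stop("ground-truth axes must be at least 15 degrees apart")
  structure(list(v_hem = v_hem, v_dab = v_dab,
                 hem_conc = hem_conc, dab_conc = dab_conc,
                 frac = fr, core_dirichlet = core_dirichlet,
                 noise_sd = noise_sd, glass_noise_sd = glass_noise_sd,
                 n_cores = as.integer(n_cores),
                 tile_px = as.integer(tile_px), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Batch perturbation
#'
#' Describes how a second staining batch deviates from the reference:
#' in-plane rotations of the stain axes (positive angles rotate an axis
#' toward the other stain's axis), optional monotone per-channel intensity
#' maps applied to the true concentrations, and an optional additive SDA
#' tint on stained pixels (yellowing).
#'
#' @param rotation_deg_hem,rotation_deg_dab in-plane rotation angles in
#'   degrees.
#' @param intensity_map_hem,intensity_map_dab optional monotone functions
#'   mapping nonnegative concentrations to nonnegative concentrations.
#' @param yellowing_shift optional length-3 additive SDA tint.
#' @return list of class `batch_perturbation`.
#' @export
batch_perturbation <- function(rotation_deg_hem = 0,
                               rotation_deg_dab = 0,
                               intensity_map_hem = NULL,
                               intensity_map_dab = NULL,
                               yellowing_shift = NULL) {
  stopifnot(is.null(intensity_map_hem) || is.function(intensity_map_hem),
            is.null(intensity_map_dab) || is.function(intensity_map_dab),
            is.null(yellowing_shift) || length(yellowing_shift) == 3L)
  structure(list(rotation_deg_hem = rotation_deg_hem,
                 rotation_deg_dab = rotation_deg_dab,
                 intensity_map_hem = intensity_map_hem,
                 intensity_map_dab = intensity_map_dab,
                 yellowing_shift = yellowing_shift),
            class = "batch_perturbation")
}

# rotate unit axis v within span{v, other} by theta degrees toward `other`
rotate_axis_in_plane <- function(v, other, theta_deg) {
  if (theta_deg == 0) return(v)
  w <- other - sum(other * v) * v
  w <- unitize(w)
  th <- theta_deg * pi / 180
  vn <- cos(th) * v + sin(th) * w
  if (any(vn < -1e-9))
    stop("perturbed axis leaves the nonnegative octant")
  unitize(pmax(vn, 0))
}

# dirichlet draw via gamma
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

#' Generate a synthetic tiled reference with ground truth
#'
#' Draws, per core, pixel classes (background / HEM-only / DAB-only /
#' mixed) with core-specific proportions and gamma concentrations, renders
#' `SDA = c_hem * v_hem + c_dab * v_dab + noise` (clipped nonnegative) and
#' converts to 8-bit sRGB against a pure-white background.  The same
#' `spec` and seed always reproduce the same image bit for bit, and the
#' random draws do not depend on `perturbation`, so a perturbed batch
#' carries *identical* per-core biology -- exactly the property consecutive
#' TMA slices provide in a real experiment.
#'
#' @param spec a [synthetic_spec()].
#' @param perturbation optional [batch_perturbation()] applied at the
#'   rendering stage ([perturb_batch()] is the convenience wrapper).
#' @param pixel_truth keep per-pixel ground truth (class and concentration
#'   matrices)?  Disable for very large references to save memory.
#' @return list with `reference` (a `tiled_reference`), `background` (the
#'   white [sda_background()] used for rendering), `core_truth`
#'   (data.frame: `core_id`, `li`, `qs`, `n_tissue_px`, `n_positive_px`)
#'   and, if `pixel_truth`, `truth` (list of `H x W` matrices `class`
#'   (0 = background, 1 = HEM-only, 2 = DAB-only, 3 = mixed), `hem_conc`,
#'   `dab_conc`).
#' @export
generate_reference <- function(spec, perturbation = NULL, pixel_truth = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(perturbation))
    stopifnot(inherits(perturbation, "batch_perturbation"))
  tp <- spec$tile_px
  npx <- tp * tp
  white <- sda_background(c(1, 1, 1))

  a <- spec$v_hem
  b <- spec$v_dab
  if (!is.null(perturbation)) {
    a <- rotate_axis_in_plane(spec$v_hem, spec$v_dab, perturbation$rotation_deg_hem)
    b <- rotate_axis_in_plane(spec$v_dab, spec$v_hem, perturbation$rotation_deg_dab)
    if (angle_deg(a, b) < 1) stop("perturbed axes are collinear")
  }

  crops <- vector("list", spec$n_cores)
  truth_class <- if (pixel_truth) vector("list", spec$n_cores)
  truth_hem <- if (pixel_truth) vector("list", spec$n_cores)
  truth_dab <- if (pixel_truth) vector("list", spec$n_cores)
  core_rows <- vector("list", spec$n_cores)

  # each tile holds a centred circular tissue core; the glass margin
  # outside the disc realises frac_background (contiguous, as on a slide)
  if (spec$frac[1] < 1 - pi / 4)
    stop("frac_background too small for a circular core inside a square tile")
  disc_r <- tp * sqrt((1 - spec$frac[1]) / pi)
  rc <- (row(matrix(0, tp, tp)) - (tp + 1) / 2)^2 +
        (col(matrix(0, tp, tp)) - (tp + 1) / 2)^2
  in_disc <- as.vector(rc) <= disc_r^2
  n_in <- sum(in_disc)
  tissue_frac <- spec$frac[2:4] / sum(spec$frac[2:4])

  with_local_seed(spec$seed, {
    for (i in seq_len(spec$n_cores)) {
      fr <- rdirichlet1(spec$core_dirichlet * tissue_frac)
      cls <- integer(npx)
      cls[in_disc] <- sample.int(3L, n_in, replace = TRUE, prob = fr)
      c_hem <- numeric(npx)
      c_dab <- numeric(npx)
      hem_carrier <- cls == 1L | cls == 3L
      dab_carrier <- cls == 2L | cls == 3L
      c_hem[hem_carrier] <- spec$hem_conc$min +
        stats::rgamma(sum(hem_carrier), spec$hem_conc$shape,
                      scale = spec$hem_conc$scale)
      c_dab[dab_carrier] <- spec$dab_conc$min +
        stats::rgamma(sum(dab_carrier), spec$dab_conc$shape,
                      scale = spec$dab_conc$scale)
      noise <- matrix(stats::rnorm(npx * 3L), npx, 3L) *
        ifelse(cls == 0L, spec$glass_noise_sd, spec$noise_sd)

      # rendering (deterministic given the draws above)
      rh <- c_hem
      rd <- c_dab
      if (!is.null(perturbation)) {
        if (!is.null(perturbation$intensity_map_hem))
          rh[hem_carrier] <- perturbation$intensity_map_hem(rh[hem_carrier])
        if (!is.null(perturbation$intensity_map_dab))
          rd[dab_carrier] <- perturbation$intensity_map_dab(rd[dab_carrier])
        if (any(rh < 0) || any(rd < 0))
          stop("intensity map produced negative concentrations")
      }
      sda <- rh %o% a + rd %o% b + noise
      if (!is.null(perturbation) && !is.null(perturbation$yellowing_shift)) {
        stained <- cls != 0L
        sda[stained, ] <- sda[stained, ] +
          rep(perturbation$yellowing_shift, each = sum(stained))
      }
      sda <- pmax(sda, 0)
      rgbm <- sda_to_rgb(sda, white)
      crops[[i]] <- rgb_image(array(rgbm, dim = c(tp, tp, 3L)))

      n_tissue <- sum(cls != 0L)
      n_pos <- sum(dab_carrier)
      core_rows[[i]] <- data.frame(
        core_id = i,
        li = if (n_tissue > 0) 100 * n_pos / n_tissue else NA_real_,
        qs = if (n_tissue > 0) sum(c_dab[dab_carrier]) / n_tissue else NA_real_,
        n_tissue_px = n_tissue, n_positive_px = n_pos)
      if (pixel_truth) {
        truth_class[[i]] <- matrix(cls, tp, tp)
        truth_hem[[i]] <- matrix(c_hem, tp, tp)
        truth_dab[[i]] <- matrix(c_dab, tp, tp)
      }
    }
  })

  tiled <- build_tiled_reference(crops, tp)
  out <- list(reference = tiled, background = white,
              core_truth = do.call(rbind, core_rows),
              axes = list(hem = a, dab = b))
  if (pixel_truth) {
    d <- dim(tiled$image)
    assemble <- function(tiles, init) {
      m <- matrix(init, d[1], d[2])
      for (i in seq_len(tiled$n_tiles)) {
        r0 <- tiled$tile_origins[i, 1]; c0 <- tiled$tile_origins[i, 2]
        m[r0:(r0 + tp - 1L), c0:(c0 + tp - 1L)] <- tiles[[i]]
      }
      m
    }
    out$truth <- list(class = assemble(truth_class, 0L),
                      hem_conc = assemble(truth_hem, 0),
                      dab_conc = assemble(truth_dab, 0))
  }
  out
}

#' @rdname generate_reference
#' @details `perturb_batch(spec, perturbation)` regenerates the *same*
#'   per-core ground truth (same seed) rendered under the perturbation, so
#'   the true biology is identical across batches.  An identity
#'   perturbation reproduces the reference bit for bit.
#' @export
perturb_batch <- function(spec, perturbation, pixel_truth = TRUE) {
  generate_reference(spec, perturbation = perturbation,
                     pixel_truth = pixel_truth)
}
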