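# Blind extraction of the hematoxylin (HEM, blue) and DAB (brown) colour
# axes from a pixel sample in SDA space.  Five unsupervised variants are
# provided: the PCA/angle-quantile method ("macenko"), an HSV-hue
# clustering initialisation ("li_init"), that initialisation refined by
# plain NMF ("li_init_nmf"), and sparse NMF started either from a standard
# NNDSVD initialisation ("snmf") or from the HSV initialisation
# ("li_init_snmf").  Two-stain brightfield pixels live near a 2-D cone in
# SDA space; all methods estimate the two edges of that cone.

#' Configuration for stain-vector extraction
#'
#' @param angle_quantile quantile of the pixel-angle distribution used by
#'   the PCA method to place the stain axes (default 0.01, i.e. 1\% of
#'   non-background training pixels fall outside each axis; use a smaller
#'   value such as 0.002 when one stain is rare).
#' @param sample_fraction fraction of reference pixels used for training
#'   (default 0.001, ~25,000 pixels on a 100-core tiled reference).
#' @param snmf_sparsity,snmf_regularisation sparse-NMF penalty weights
#'   (column-sparsity on coefficients, ridge on the mixing matrix).
#' @param nmf_max_iter,nmf_tol multiplicative-update budget and relative
#'   residual-change convergence tolerance.
#' @param background_sda_threshold pixels whose SDA vector norm is at or
#'   below this value are treated as unstained background (default 0.015,
#'   the same radius used for tissue segmentation).
#' @param seed integer seed for the clustering initialisation.
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(angle_quantile = 0.01,
                              sample_fraction = 0.001,
                              snmf_sparsity = 0.005,
                              snmf_regularisation = 0.01,
                              nmf_max_iter = 2000L,
                              nmf_tol = 1e-6,
                              background_sda_threshold = 0.015,
                              seed = 1L) {
  stopifnot(angle_quantile > 0, angle_quantile < 0.5,
            sample_fraction > 0, sample_fraction <= 1,
            snmf_sparsity >= 0, snmf_regularisation >= 0,
            nmf_max_iter >= 1, nmf_tol > 0, background_sda_threshold >= 0)
  structure(list(angle_quantile = angle_quantile,
                 sample_fraction = sample_fraction,
                 snmf_sparsity = snmf_sparsity,
                 snmf_regularisation = snmf_regularisation,
                 nmf_max_iter = as.integer(nmf_max_iter),
                 nmf_tol = nmf_tol,
                 background_sda_threshold = background_sda_threshold,
                 seed = as.integer(seed)),
            class = "extraction_config")
}

#' Stain basis (colour deconvolution matrix)
#'
#' Holds the unit HEM axis `a`, unit DAB axis `b`, their cross product `c`
#' (kept as a residual/quality-control axis), and the deconvolution matrix
#' `M = [a b c]`.
#'
#' @param a,b nonnegative unit 3-vectors (HEM and DAB axes).
#' @param method method tag, one of `macenko`, `li_init`, `li_init_nmf`,
#'   `snmf`, `li_init_snmf` (or `manual`).
#' @return object of class `stain_basis`.
#' @export
stain_basis <- function(a, b, method = "manual") {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L)
  if (any(a < -1e-9) || any(b < -1e-9))
    stop("stain axes must be componentwise nonnegative")
  a <- pmax(a, 0); b <- pmax(b, 0)
  if (abs(vnorm(a) - 1) > 1e-6 || abs(vnorm(b) - 1) > 1e-6)
    stop("stain axes must be unit vectors")
  cc <- cross3(a, b)
  if (vnorm(cc) < 1e-6)
    stop("collinear stain axes: degenerate basis")
  structure(list(a = a, b = b, c = cc, M = cbind(a, b, cc),
                 method_tag = method),
            class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat(sprintf("<stain_basis> method = %s\n", x$method_tag))
  m <- rbind(HEM = x$a, DAB = x$b, residual = x$c)
  colnames(m) <- c("R", "G", "B")
  print(round(m, 4))
  cat(sprintf("angle(HEM, DAB) = %.1f deg\n", angle_deg(x$a, x$b)))
  invisible(x)
}

#' Assign HEM/DAB labels to two extracted stain vectors
#'
#' Hematoxylin appears blue, so it absorbs strongly in the red channel and
#' weakly in blue: the vector with the larger red-to-blue SDA-component
#' ratio is labelled HEM, the other DAB.  Ties are broken by assigning the
#' vector with the larger green component to DAB.  This replaces the visual
#' assignment a human would do from the pixel-cloud plots.
#'
#' @param u,v nonnegative unit 3-vectors, non-collinear.
#' @return list with elements `a` (HEM) and `b` (DAB).
#' @export
order_stain_vectors <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (vnorm(cross3(u, v)) < 1e-6) stop("collinear stain vectors")
  eps <- 1e-9
  ru <- (u[1] + eps) / (u[3] + eps)
  rv <- (v[1] + eps) / (v[3] + eps)
  if (abs(ru - rv) < 1e-12) {
    if (u[2] > v[2]) list(a = v, b = u) else list(a = u, b = v)
  } else if (ru > rv) {
    list(a = u, b = v)
  } else {
    list(a = v, b = u)
  }
}

# drop (near-)unstained pixels; x is an n x 3 SDA matrix
drop_background_pixels <- function(x, threshold) {
  norms <- sqrt(rowSums(x^2))
  x[norms > threshold, , drop = FALSE]
}

#' PCA / angle-quantile stain extraction
#'
#' Two-stain pixel clouds in SDA space lie almost entirely in a plane
#' through the origin (the explained variance of the first two principal
#' components nears 100\%).  After discarding background pixels, PCA
#' identifies that plane; the two principal directions are translated to
#' the origin, each pixel's in-plane angle to the first component is
#' computed, and the stain axes are placed at the `angle_quantile` and
#' `1 - angle_quantile` quantiles of the angle distribution.  By
#' construction about `angle_quantile` of the training pixels then carry a
#' (small) negative coefficient in each deconvoluted channel; these mark
#' negligible contributions and can be clipped to zero downstream.
#'
#' @param pixels `n x 3` matrix of SDA triples.
#' @param config an [extraction_config()].
#' @return a [stain_basis()] with attributes `explained_variance_2pc`
#'   (fraction of variance in the first two components) and
#'   `n_training` (non-background pixels used).
#' @export
extract_macenko <- function(pixels, config = extraction_config()) {
  nb <- drop_background_pixels(pixels, config$background_sda_threshold)
  if (nrow(nb) < 100L)
    stop("need at least 100 non-background pixels, got ", nrow(nb))
  pc <- stats::prcomp(nb, center = TRUE, scale. = FALSE)
  ev2 <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  if (pc$sdev[2] < 1e-8 * pc$sdev[1])
    stop("degenerate colour plane: pixel cloud is rank 1 (single stain?)")
  p1 <- pc$rotation[, 1]
  p2 <- pc$rotation[, 2]
  # orient the first component along the data so angles are well defined
  if (mean(nb %*% p1) < 0) p1 <- -p1
  t1 <- as.vector(nb %*% p1)
  t2 <- as.vector(nb %*% p2)
  ang <- atan2(t2, t1)
  q <- stats::quantile(ang, c(config$angle_quantile, 1 - config$angle_quantile),
                       names = FALSE)
  v1 <- cos(q[1]) * p1 + sin(q[1]) * p2
  v2 <- cos(q[2]) * p1 + sin(q[2]) * p2
  fix <- function(v) {
    if (sum(v) < 0) v <- -v
    unitize(pmax(v, 0))
  }
  ord <- order_stain_vectors(fix(v1), fix(v2))
  basis <- stain_basis(ord$a, ord$b, method = "macenko")
  attr(basis, "explained_variance_2pc") <- ev2
  attr(basis, "n_training") <- nrow(nb)
  basis
}

# circular k-means (k = 2) on hue: Lloyd iterations on the unit circle with
# deterministic multi-start.  Returns integer cluster labels.
circular_kmeans2 <- function(hue, seed, n_start = 5L, max_iter = 50L) {
  pts <- cbind(cos(2 * pi * hue), sin(2 * pi * hue))
  if (nrow(unique(round(pts, 10))) < 2L)
    stop("degenerate cluster: all pixels share a single hue")
  best <- NULL
  best_wss <- Inf
  with_local_seed(seed, {
    for (s in seq_len(n_start)) {
      ctr <- pts[sample.int(nrow(pts), 2L), , drop = FALSE]
      for (it in seq_len(max_iter)) {
        d1 <- (pts[, 1] - ctr[1, 1])^2 + (pts[, 2] - ctr[1, 2])^2
        d2 <- (pts[, 1] - ctr[2, 1])^2 + (pts[, 2] - ctr[2, 2])^2
        lab <- ifelse(d1 <= d2, 1L, 2L)
        if (length(unique(lab)) < 2L) break
        new_ctr <- rbind(colMeans(pts[lab == 1L, , drop = FALSE]),
                         colMeans(pts[lab == 2L, , drop = FALSE]))
        # project centroids back to the circle (circular mean)
        nn <- sqrt(rowSums(new_ctr^2))
        if (any(nn < 1e-12)) break
        new_ctr <- new_ctr / nn
        if (max(abs(new_ctr - ctr)) < 1e-10) { ctr <- new_ctr; break }
        ctr <- new_ctr
      }
      if (length(unique(lab)) < 2L) next
      wss <- sum(pmin(d1, d2))
      if (wss < best_wss) { best_wss <- wss; best <- lab }
    }
  })
  if (is.null(best)) stop("degenerate cluster: hue clustering failed")
  best
}

#' HSV-clustering initialisation for stain vectors
#'
#' Partitions non-background pixels into two clusters by hue (circular
#' k-means on the unit circle), takes the componentwise median RGB of each
#' cluster as its representative colour, converts the two representatives
#' to SDA and normalises them into initial HEM/DAB axes.  Useful on its own
#' and as the initialisation for the NMF/SNMF refinements.
#'
#' @param pixels `n x 3` matrix of raw 8-bit RGB triples.
#' @param background an [sda_background()].
#' @param config an [extraction_config()].
#' @return a [stain_basis()] (method tag `li_init`).
#' @export
extract_li_init <- function(pixels, background, config = extraction_config()) {
  sda <- rgb_to_sda(pixels, background)
  keep <- sqrt(rowSums(sda^2)) > config$background_sda_threshold
  if (sum(keep) < 100L)
    stop("need at least 100 non-background pixels, got ", sum(keep))
  rgb_nb <- pixels[keep, , drop = FALSE]
  hsv <- grDevices::rgb2hsv(t(rgb_nb), maxColorValue = 255)
  lab <- circular_kmeans2(hsv["h", ], seed = config$seed)
  rep_sda <- lapply(1:2, function(k) {
    members <- rgb_nb[lab == k, , drop = FALSE]
    med <- apply(members, 2, stats::median)
    as.vector(rgb_to_sda(matrix(med, nrow = 1), background))
  })
  v1 <- rep_sda[[1]]; v2 <- rep_sda[[2]]
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9)
    stop("degenerate cluster: a cluster representative is unstained")
  ord <- order_stain_vectors(unitize(pmax(v1, 0)), unitize(pmax(v2, 0)))
  stain_basis(ord$a, ord$b, method = "li_init")
}

# shared multiplicative-update engine for NMF (lambda = eta = 0) and SNMF.
# X is 3 x n; M0 is 3 x 2 with unit columns.  Minimises
#   ||X - M C||_F^2 + lambda ||M||_F^2 + eta sum_j (sum_i C_ij)^2,  M, C >= 0.
run_mf <- function(X, M0, lambda, eta, max_iter, tol) {
  eps <- 1e-12
  M <- M0
  # nonnegative least-squares-ish start for C
  C <- pmax(solve(crossprod(M) + diag(1e-10, 2), t(M) %*% X), eps)
  xnorm <- sqrt(sum(X^2))
  res_prev <- Inf
  converged <- FALSE
  ones2 <- matrix(1, 2, 2)
  for (it in seq_len(max_iter)) {
    C <- C * (t(M) %*% X) / (crossprod(M) %*% C + eta * (ones2 %*% C) + eps)
    M <- M * (X %*% t(C)) / (M %*% tcrossprod(C) + lambda * M + eps)
    # renormalise stain columns, pushing scale into C
    nn <- sqrt(colSums(M^2))
    nn[nn < eps] <- eps
    M <- sweep(M, 2, nn, "/")
    C <- C * nn
    res <- sqrt(sum((X - M %*% C)^2)) / max(xnorm, eps)
    if (is.finite(res_prev) && abs(res_prev - res) < tol * max(res_prev, eps)) {
      converged <- TRUE
      res_prev <- res
      break
    }
    res_prev <- res
  }
  list(M = M, C = C, residual = res_prev, iterations = it, converged = converged)
}

finish_mf_basis <- function(fit, method, warn_label) {
  if (!fit$converged)
    warning(warn_label, " did not converge within the iteration budget; ",
            "returning the best iterate")
  ord <- order_stain_vectors(unitize(pmax(fit$M[, 1], 0)),
                             unitize(pmax(fit$M[, 2], 0)))
  basis <- stain_basis(ord$a, ord$b, method = method)
  attr(basis, "converged") <- fit$converged
  attr(basis, "iterations") <- fit$iterations
  attr(basis, "residual") <- fit$residual
  basis
}

#' Refine stain axes by non-negative matrix factorisation
#'
#' Factorises the non-background SDA pixel matrix `X (3 x n)` as
#' `X ~ M C` with `M, C >= 0` by multiplicative (Lee-Seung) updates,
#' starting from the given basis.  Columns of `M` are renormalised to unit
#' length each sweep.  NMF is initialisation-dependent; a good start (e.g.
#' [extract_li_init()]) is required in practice, and even then plain NMF
#' may drift the axes into the pixel cloud rather than to its edges.
#'
#' @param pixels `n x 3` matrix of SDA triples.
#' @param init a [stain_basis()] initialisation.
#' @param config an [extraction_config()].
#' @return a [stain_basis()] (method tag `li_init_nmf`) with attributes
#'   `converged`, `iterations` and `residual`.
#' @export
refine_nmf <- function(pixels, init, config = extraction_config()) {
  stopifnot(inherits(init, "stain_basis"))
  nb <- drop_background_pixels(pixels, config$background_sda_threshold)
  if (nrow(nb) < 100L)
    stop("need at least 100 non-background pixels, got ", nrow(nb))
  fit <- run_mf(t(nb), cbind(init$a, init$b), lambda = 0, eta = 0,
                max_iter = config$nmf_max_iter, tol = config$nmf_tol)
  finish_mf_basis(fit, "li_init_nmf", "NMF")
}

# NNDSVD initialisation (nonnegative double SVD) for rank-2 factorisation
nndsvd_init <- function(X, k = 2L) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    mp <- vnorm(up) * vnorm(vp)
    mn <- vnorm(un) * vnorm(vn)
    if (mp >= mn && mp > 0) {
      W[, j] <- sqrt(s$d[j] * mp) * up / vnorm(up)
    } else if (mn > 0) {
      W[, j] <- sqrt(s$d[j] * mn) * un / vnorm(un)
    } else {
      W[, j] <- abs(s$u[, j])
    }
  }
  W
}

#' Refine stain axes by sparse NMF
#'
#' Minimises `||X - M C||_F^2 + lambda ||M||_F^2 + eta sum_j ||C[, j]||_1^2`
#' subject to `M, C >= 0` (multiplicative updates), where `lambda` is
#' `snmf_regularisation` and `eta` is `snmf_sparsity`.  With both penalties
#' zero this reduces exactly to [refine_nmf()].  The start is either a
#' [stain_basis()] (typically from [extract_li_init()], method tag
#' `li_init_snmf`) or the string `"standard"` for an NNDSVD initialisation
#' computed from the data (method tag `snmf`).  The penalty balance must be
#' tuned per application; the defaults are a starting point, not a claim.
#'
#' @param pixels `n x 3` matrix of SDA triples.
#' @param init a [stain_basis()] or `"standard"`.
#' @param config an [extraction_config()].
#' @return a [stain_basis()] with attributes `converged`, `iterations`,
#'   `residual`.
#' @export
refine_snmf <- function(pixels, init = "standard", config = extraction_config()) {
  nb <- drop_background_pixels(pixels, config$background_sda_threshold)
  if (nrow(nb) < 100L)
    stop("need at least 100 non-background pixels, got ", nrow(nb))
  X <- t(nb)
  if (inherits(init, "stain_basis")) {
    M0 <- cbind(init$a, init$b)
    tag <- "li_init_snmf"
  } else if (identical(init, "standard")) {
    M0 <- nndsvd_init(X, 2L)
    nn <- sqrt(colSums(M0^2))
    if (any(nn < 1e-12)) stop("degenerate NNDSVD initialisation")
    M0 <- sweep(M0, 2, nn, "/")
    tag <- "snmf"
  } else stop("init must be a stain_basis or \"standard\"")
  fit <- run_mf(X, M0, lambda = config$snmf_regularisation,
                eta = config$snmf_sparsity,
                max_iter = config$nmf_max_iter, tol = config$nmf_tol)
  finish_mf_basis(fit, tag, "SNMF")
}

#' Quality of the extracted stain plane
#'
#' Deconvolves the non-background pixels with the basis and returns the
#' ratio of the mean absolute residual (third-axis) coefficient to the mean
#' in-plane coefficient norm.  Pixels of a genuine two-stain image lie
#' almost in the HEM-DAB plane, so small values indicate a good basis.
#'
#' @param pixels `n x 3` matrix of SDA triples.
#' @param basis a [stain_basis()].
#' @param background_sda_threshold background cut-off (SDA norm).
#' @return nonnegative scalar; 0 when all pixels lie exactly in the plane.
#' @export
plane_quality <- function(pixels, basis, background_sda_threshold = 0.015) {
  nb <- drop_background_pixels(pixels, background_sda_threshold)
  if (nrow(nb) == 0L) return(0)
  co <- t(solve(basis$M, t(nb)))
  mean(abs(co[, 3])) / max(mean(sqrt(co[, 1]^2 + co[, 2]^2)), 1e-12)
}

#' Extract stain vectors from a reference image
#'
#' User-level dispatcher over the five extraction methods.  Handles
#' background estimation, regular pixel sampling at the configured training
#' fraction, the SDA transform, and method dispatch.
#'
#' @param image an [rgb_image()] or `tiled_reference`.
#' @param method one of `"macenko"`, `"li-init"`, `"li-init-nmf"`,
#'   `"snmf"`, `"li-init-snmf"`.
#' @param config an [extraction_config()].
#' @param background optional [sda_background()]; estimated from the image
#'   when missing.
#' @return a [stain_basis()].
#' @export
extract_stains <- function(image,
                           method = c("macenko", "li-init", "li-init-nmf",
                                      "snmf", "li-init-snmf"),
                           config = extraction_config(),
                           background = NULL) {
  method <- match.arg(method)
  if (inherits(image, "tiled_reference")) image <- image$image
  stopifnot(inherits(image, "rgb_image"))
  if (is.null(background))
    background <- estimate_background(image)$background
  rgb_px <- sample_pixels(image, config$sample_fraction)
  basis <- extract_stains_pixels(rgb_px, background, method, config)
  attr(basis, "background") <- background
  basis
}

# method dispatch on an already-sampled n x 3 raw-RGB pixel matrix
extract_stains_pixels <- function(rgb_px, background, method, config) {
  sda_px <- rgb_to_sda(rgb_px, background)
  switch(method,
    "macenko" = extract_macenko(sda_px, config),
    "li-init" = extract_li_init(rgb_px, background, config),
    "li-init-nmf" = refine_nmf(sda_px,
                               extract_li_init(rgb_px, background, config),
                               config),
    "snmf" = refine_snmf(sda_px, "standard", config),
    "li-init-snmf" = refine_snmf(sda_px,
                                 extract_li_init(rgb_px, background, config),
                                 config))
}

#' Serialise a stain basis to JSON
#'
#' @param basis a [stain_basis()].
#' @param path output JSON path.
#' @return `path` (write) or a [stain_basis()] (read).
#' @export
write_stain_basis <- function(basis, path) {
  jsonlite::write_json(list(a = basis$a, b = basis$b, c = basis$c,
                            method = basis$method_tag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_basis
#' @export
read_stain_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_basis(obj$a, obj$b, method = obj$method)
}
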