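# End-to-end pipeline: extraction -> colour matching -> QC -> optional
# distribution fitting -> QC -> normalised images -> quantification.

#' Run the full normalisation pipeline over several batches
#'
#' Fits a [stain_norm()] transform from every batch to the designated
#' target, writes the stain bases, fits and three-stage QC reports, the
#' normalised reference images, and (when segmentation parameters are
#' supplied and references are tiled) per-core LI/QS features with
#' between-batch comparisons.
#'
#' @param batches named list of batch references ([rgb_image()],
#'   `tiled_reference` or paths); the element named by `target` is the
#'   target batch.
#' @param target name of the target batch in `batches`.
#' @param out_dir output directory (created if needed); set `NULL` to skip
#'   writing files.
#' @param method,fit,config,n_quantiles,n_splines passed to [stain_norm()].
#' @param seg_params optional [segmentation_params()] (set on the target
#'   batch and reused unchanged on every normalised batch).
#' @param nuclear is the marker nuclear?
#' @return invisibly, a list with per-batch `stain_norm` fits, the pooled
#'   QC table, per-batch core features and feature comparisons.
#' @export
run_pipeline <- function(batches, target, out_dir = NULL,
                         method = "macenko", fit = "none",
                         config = extraction_config(),
                         n_quantiles = 1000L, n_splines = 100L,
                         seg_params = NULL, nuclear = FALSE) {
  stopifnot(target %in% names(batches), length(batches) >= 2L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tgt <- batches[[target]]
  others <- setdiff(names(batches), target)

  fits <- list()
  qc_rows <- list()
  features <- list()
  comparisons <- list()

  tgt_features <- NULL
  if (!is.null(seg_params) && inherits(tgt, "tiled_reference")) {
    bg_t <- estimate_background(tgt$image)$background
    basis_t0 <- extract_stains(tgt, method, config, bg_t)
    dec_t <- deconvolve(rgb_to_sda(tgt$image, bg_t), basis_t0, clip = TRUE)
    tgt_features <- per_core_features(tgt, dec_t, seg_params, nuclear)
    features[[target]] <- tgt_features
  }

  for (nm in others) {
    message("normalising batch '", nm, "' to target '", target, "'")
    sn <- stain_norm(batches[[nm]], tgt, method = method, fit = fit,
                     config = config, n_quantiles = n_quantiles,
                     n_splines = n_splines)
    fits[[nm]] <- sn
    qc_tab <- summary(sn)$qc_table
    qc_tab$batch <- nm
    qc_rows[[nm]] <- qc_tab

    if (!is.null(out_dir)) {
      write_stain_basis(sn$basis$source, file.path(out_dir, paste0("basis_", nm, ".json")))
      write_stain_basis(sn$basis$target, file.path(out_dir, paste0("basis_", target, ".json")))
      if (!is.null(sn$fits))
        write_channel_fits(sn$fits, file.path(out_dir, paste0("fits_", nm, ".json")))
      img <- resolve_image(batches[[nm]])
      norm <- predict(sn, img)
      write_image(norm$normalised, file.path(out_dir, paste0("normalised_", nm, ".tiff")))
    }

    if (!is.null(seg_params) && inherits(batches[[nm]], "tiled_reference")) {
      norm <- predict(sn, batches[[nm]]$image)
      features[[nm]] <- per_core_features(batches[[nm]], norm$deconvolved,
                                          seg_params, nuclear)
      if (!is.null(tgt_features)) {
        comparisons[[nm]] <- rbind(
          compare_feature_distributions(features[[nm]], tgt_features, "li"),
          compare_feature_distributions(features[[nm]], tgt_features, "qs"))
      }
    }
  }

  qc_table <- do.call(rbind, qc_rows)
  rownames(qc_table) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(qc_table, file.path(out_dir, "qc.csv"), row.names = FALSE)
    for (nm in names(features))
      utils::write.csv(features[[nm]],
                       file.path(out_dir, paste0("features_", nm, ".csv")),
                       row.names = FALSE)
    if (length(comparisons))
      utils::write.csv(do.call(rbind, comparisons),
                       file.path(out_dir, "feature_comparisons.csv"),
                       row.names = FALSE)
  }
  invisible(list(fits = fits, qc = qc_table, features = features,
                 comparisons = comparisons))
}
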