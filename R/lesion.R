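# Hemispheric-asymmetry lesion segmentation: absolute difference map against
# the registered mirror image, percentile thresholding over the brain mask,
# hypodense-side restriction, and minimum-cluster-size filtering; plus the
# end-to-end scan quantification and QC overlay.

#' Binary lesion mask
#'
#' @param voxels logical 3-D array.
#' @param spacing mm per axis.
#' @param provenance list of configuration / stage information.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, spacing, provenance = list()) {
  if (!is.logical(voxels) || length(dim(voxels)) != 3)
    stop_asym("mask", "voxels must be a logical 3-D array")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d voxels set, %.2f mL\n", sum(x$voxels),
              lesion_volume_ml(x)))
  invisible(x)
}

#' Lesion volume in mL
#'
#' Number of set voxels times the voxel volume (mm^3), divided by 1000.
#'
#' @param mask a [lesion_mask()].
#' @return Volume in mL (>= 0).
#' @export
lesion_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Segment the lesion from the hemispheric-asymmetry map
#'
#' Computes the voxelwise absolute difference between the original and the
#' registered mirror image, thresholds it at the `config$percentile`-th
#' percentile of its distribution over brain-mask voxels, optionally restricts
#' to the hypodense side (`original < mirrored`), and removes connected
#' components smaller than `config$min_cluster_mm3`.
#'
#' @param original,mirrored [ct_volume()] objects on one grid (windowed
#'   intensities).
#' @param brain_mask non-empty logical array on the same grid.
#' @param config a [segmentation_config()].
#' @return A [lesion_mask()]; its provenance records the threshold value, the
#'   pre-filter supra-threshold voxel count and the cluster census.
#' @export
asymmetry_lesion_mask <- function(original, mirrored, brain_mask,
                                  config = segmentation_config()) {
  stopifnot(inherits(original, "ct_volume"), inherits(mirrored, "ct_volume"))
  if (!all(dim(original$voxels) == dim(mirrored$voxels)))
    stop_asym("asymmetry", "original and mirrored must share one grid")
  if (!any(brain_mask)) stop_asym("asymmetry", "brain mask is empty")
  dmap <- abs(original$voxels - mirrored$voxels)
  vals <- dmap[brain_mask]
  qc <- list(config = unclass(config))
  if (all(vals == 0)) {
    qc$note <- "all-zero difference map"
    return(lesion_mask(array(FALSE, dim(dmap)), spacing = original$spacing,
                       provenance = qc))
  }
  thr <- quantile(vals, config$percentile / 100, names = FALSE, type = 7)
  supra <- brain_mask & (dmap > thr)
  qc$threshold <- thr
  qc$n_suprathreshold <- sum(supra)
  qc$n_brain <- sum(brain_mask)
  if (config$side_rule) supra <- supra & (original$voxels < mirrored$voxels)
  lab <- .cpp_label_components(supra, dim(supra), config$connectivity)
  keep <- array(FALSE, dim(supra))
  if (max(lab) > 0) {
    sizes <- tabulate(lab)
    min_vox <- config$min_cluster_mm3 / prod(original$spacing)
    ok <- which(sizes >= min_vox)
    if (length(ok)) keep <- array(lab %in% ok, dim(supra))
    qc$n_clusters_prefilter <- length(sizes)
    qc$n_clusters <- length(ok)
  } else {
    qc$n_clusters_prefilter <- 0L
    qc$n_clusters <- 0L
  }
  lesion_mask(keep, spacing = original$spacing, provenance = qc)
}

mask_laterality <- function(mask, affine) {
  if (!any(mask$voxels)) return("none")
  idx <- which(mask$voxels, arr.ind = TRUE) - 1
  wx <- voxel_to_world(affine, idx)[, 1]
  m <- mean(wx)
  if (abs(m) < 1e-6) "none" else if (m < 0) "left" else "right"
}

#' Quantify infarct volume from a head CT scan
#'
#' Runs the full hemispheric-asymmetry workflow: reorient to RAS+, CT skull
#' strip, resample to isotropic resolution, HU windowing, registration of the
#' left-right flip, asymmetry-map thresholding with cluster filtering, volume
#' measurement and optional rigid template alignment. Deterministic for a
#' fixed input and configuration.
#'
#' @param x path to a NIfTI file, or a [ct_volume()].
#' @param config a [segmentation_config()].
#' @param template optional template [ct_volume()] for spatial
#'   standardization of the mask.
#' @param mask_out optional path to write the lesion mask (NIfTI).
#' @param qc_out optional path to write a QC overlay (PNG).
#' @return A `lesion_report`: `volume_ml`, `n_clusters`, `largest_cluster_ml`,
#'   `laterality`, `qc` (brain-mask volume, registration residuals, threshold),
#'   plus the `mask` itself.
#' @export
quantify_scan <- function(x, config = segmentation_config(), template = NULL,
                          mask_out = NULL, qc_out = NULL) {
  vol <- if (inherits(x, "ct_volume")) x else read_nifti(x)
  vol <- reorient_to_standard(vol)
  brain0 <- skull_strip_ct(vol, config)
  brain_vol0 <- ct_volume(array(as.numeric(brain0), dim(brain0)),
                          spacing = vol$spacing, affine = vol$affine)
  vol_iso <- resample_isotropic(vol, config$iso_spacing)
  brain_iso <- resample_isotropic(brain_vol0, config$iso_spacing, outside = 0)
  brain <- brain_iso$voxels > 0.5
  win <- window_hu(vol_iso, config$hu_window)
  reg <- register_flipped(win, brain_mask = brain)
  # carry the brain mask into halfway space along with the image pair
  brain_half <- if (all(reg$half_matrix == diag(4))) brain else {
    A <- win$affine
    bm <- resample_index_map(
      ct_volume(array(as.numeric(brain), dim(brain)), spacing = win$spacing,
                affine = A),
      solve(A) %*% reg$half_matrix %*% A, dim(brain), win$spacing, A,
      outside = 0, nearest = TRUE)
    bm$voxels > 0.5
  }
  mask <- asymmetry_lesion_mask(reg$original, reg$mirrored, brain_half, config)
  if (!is.null(template)) {
    al <- align_to_template(vol_iso, mask, template)
    mask_std <- al$mask
  } else mask_std <- NULL
  lab <- .cpp_label_components(mask$voxels, dim(mask$voxels),
                               config$connectivity)
  sizes <- if (max(lab) > 0) tabulate(lab) else integer(0)
  vml <- lesion_volume_ml(mask)
  report <- structure(list(
    volume_ml = vml,
    n_clusters = length(sizes),
    largest_cluster_ml = if (length(sizes)) max(sizes) *
      prod(mask$spacing) / 1000 else 0,
    laterality = mask_laterality(mask, vol_iso$affine),
    qc = list(brain_mask_ml = sum(brain) * prod(vol_iso$spacing) / 1000,
              registration_residual = reg$residual,
              registration_residual_init = reg$residual_init,
              registration_converged = reg$converged,
              threshold = mask$provenance$threshold %||% NA_real_,
              n_suprathreshold = mask$provenance$n_suprathreshold %||% 0L,
              n_brain = mask$provenance$n_brain %||% sum(brain)),
    mask = mask, mask_template_space = mask_std), class = "lesion_report")
  if (!is.null(mask_out)) {
    write_nifti(ct_volume(array(as.numeric(mask$voxels), dim(mask$voxels)),
                          spacing = mask$spacing, affine = vol_iso$affine),
                mask_out)
  }
  if (!is.null(qc_out)) qc_overlay(vol_iso, mask, qc_out)
  report
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> %.2f mL in %d cluster(s), laterality %s\n",
              x$volume_ml, x$n_clusters, x$laterality))
  invisible(x)
}

#' Serialize a lesion report as JSON
#'
#' Deterministic (byte-identical for identical input and configuration);
#' the mask itself is omitted.
#'
#' @param report a `lesion_report`.
#' @param path optional output path.
#' @return JSON string, invisibly if `path` given.
#' @export
report_json <- function(report, path = NULL) {
  payload <- report[c("volume_ml", "n_clusters", "largest_cluster_ml",
                      "laterality")]
  payload$qc <- report$qc
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

mask_centroid_vox <- function(mask) {
  if (!any(mask$voxels)) return(round(dim(mask$voxels) / 2))
  idx <- which(mask$voxels, arr.ind = TRUE)
  round(colMeans(idx))
}

#' Write a three-panel QC overlay image
#'
#' Axial, coronal and sagittal slices through the lesion centroid (grid
#' centre if the mask is empty), with lesion voxels overdrawn in red.
#'
#' @param volume a [ct_volume()].
#' @param mask a [lesion_mask()] on the same grid.
#' @param out_path PNG output path.
#' @return List of the centroid slice indices (1-based), invisibly.
#' @export
qc_overlay <- function(volume, mask, out_path) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lesion_mask"))
  if (!all(dim(volume$voxels) == dim(mask$voxels)))
    stop_asym("qc", "volume and mask must share one grid")
  cen <- mask_centroid_vox(mask)
  ok <- tryCatch({
    png(out_path, width = 900, height = 320)
    TRUE
  }, error = function(e) stop_asym("qc", paste("cannot write", out_path)))
  on.exit(if (ok) dev.off())
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(par(op), add = TRUE)
  panels <- list(
    axial    = list(v = volume$voxels[, , cen[3]], m = mask$voxels[, , cen[3]]),
    coronal  = list(v = volume$voxels[, cen[2], ], m = mask$voxels[, cen[2], ]),
    sagittal = list(v = volume$voxels[cen[1], , ], m = mask$voxels[cen[1], , ]))
  for (nm in names(panels)) {
    p <- panels[[nm]]
    image(p$v, col = gray(seq(0, 1, length.out = 128)), axes = FALSE,
          useRaster = TRUE)
    if (any(p$m)) {
      idx <- which(p$m, arr.ind = TRUE)
      nx <- nrow(p$m); ny <- ncol(p$m)
      points((idx[, 1] - 1) / (nx - 1), (idx[, 2] - 1) / (ny - 1),
             pch = 15, cex = 0.3, col = "#d62728")
    }
    title(sprintf("%s (slice %d)", nm,
                  switch(nm, axial = cen[3], coronal = cen[2], cen[1])))
  }
  invisible(list(centroid = cen))
}
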