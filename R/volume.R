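# CT volume container and grid-level operations: reorientation to RAS+,
# isotropic resampling, HU windowing, left-right mirroring.

#' CT volume container
#'
#' A 3-D voxel grid in Hounsfield units with spacing (mm) and a voxel-to-world
#' affine (0-based voxel indices to RAS+ mm). When `affine` is omitted the grid
#' is centred on the world origin, so the mid-sagittal plane is x = 0.
#'
#' @param voxels 3-D numeric array (HU).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `affine`, `orientation_label`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(voxels)) != 3) stop_asym("volume", "voxels must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_asym("volume", "spacing must be 3 positive finite values")
  if (any(!is.finite(voxels))) stop_asym("volume", "HU values must be finite")
  if (is.null(affine)) {
    dm <- dim(voxels)
    origin <- -(dm - 1) / 2 * spacing
    affine <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop_asym("volume", "affine must be an invertible 4x4 matrix")
  structure(list(voxels = voxels, spacing = spacing, affine = affine,
                 orientation_label = orientation_label(affine)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, %s\n",
              dm[1], dm[2], dm[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation_label))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Three-letter orientation code from the affine (e.g. "RAS"); "oblique" if
# any axis is more than 1 degree off the world axes.
orientation_label <- function(affine) {
  R <- affine[1:3, 1:3]
  lab <- character(3)
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  for (j in 1:3) {
    col <- R[, j] / sqrt(sum(R[, j]^2))
    i <- which.max(abs(col))
    if (abs(col[i]) < cos(1 * pi / 180)) return("oblique")
    lab[j] <- if (col[i] > 0) pos[i] else neg[i]
  }
  paste(lab, collapse = "")
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

# world coordinates (mm) of 0-based voxel indices (n x 3 matrix)
voxel_to_world <- function(affine, idx) {
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Reorient a volume to the canonical RAS+ convention
#'
#' Permutes and flips the voxel axes so the first axis increases to the
#' patient's right, the second anteriorly and the third superiorly. World
#' coordinates of every voxel are unchanged.
#'
#' @param volume a [ct_volume()] with an axis-aligned affine (within 1 degree).
#' @return The reoriented [ct_volume()].
#' @export
reorient_to_standard <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  if (orientation_label(volume$affine) == "oblique")
    stop_asym("reorient",
              "affine is oblique (>1 degree off-axis); resample the volume first")
  R <- volume$affine[1:3, 1:3]
  perm <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    i <- which.max(abs(R[, j]))
    perm[j] <- i           # voxel axis j advances along world axis i
    sgn[j] <- sign(R[i, j])
  }
  if (length(unique(perm)) != 3) stop_asym("reorient", "degenerate affine axes")
  # order voxel axes so axis k maps to world axis k, with positive direction
  ord <- order(perm)       # new axis k comes from old axis ord[k]
  vox <- aperm(volume$voxels, ord)
  spacing <- volume$spacing[ord]
  dm_old <- dim(volume$voxels)
  # affine for permuted array: column k is old column ord[k]
  A <- volume$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, ord]
  flip_sgn <- sgn[ord]
  for (k in 1:3) {
    if (flip_sgn[k] < 0) {
      n_k <- dim(vox)[k]
      idx <- rev(seq_len(n_k))
      vox <- switch(k, vox[idx, , , drop = FALSE], vox[, idx, , drop = FALSE],
                    vox[, , idx, drop = FALSE])
      # new index i' = n-1-i  =>  col_k -> -col_k, origin += (n-1)*col_k
      A2[1:3, 4] <- A2[1:3, 4] + (n_k - 1) * A2[1:3, k]
      A2[1:3, k] <- -A2[1:3, k]
    }
  }
  ct_volume(vox, spacing = spacing, affine = A2)
}

# Internal: resample src ct_volume onto a target grid given a 4x4 matrix
# mapping output voxel index -> source voxel index.
resample_index_map <- function(src, M, out_dim, out_spacing, out_affine,
                               outside = -1000, nearest = FALSE) {
  vals <- .cpp_resample_affine(as.numeric(src$voxels), dim(src$voxels),
                               M, as.integer(out_dim), outside, nearest)
  ct_volume(array(vals, dim = out_dim), spacing = out_spacing,
            affine = out_affine)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear resampling onto an isotropic grid covering the same physical
#' extent (within one voxel). A volume already at the requested spacing is
#' returned unchanged.
#'
#' @param volume a [ct_volume()].
#' @param iso_spacing target spacing in mm (scalar, > 0).
#' @param outside fill value for out-of-grid samples (HU).
#' @return The resampled [ct_volume()] with spacing
#'   `c(iso_spacing, iso_spacing, iso_spacing)`.
#' @export
resample_isotropic <- function(volume, iso_spacing = 1.0, outside = -1000) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(iso_spacing) || length(iso_spacing) != 1 || iso_spacing <= 0)
    stop_asym("resample", "iso_spacing must be a single positive number")
  if (all(abs(volume$spacing - iso_spacing) < 1e-9)) return(volume)
  dm <- dim(volume$voxels)
  scale <- iso_spacing / volume$spacing
  out_dim <- pmax(2L, as.integer(floor((dm - 1) / scale)) + 1L)
  M <- diag(c(scale, 1))
  out_affine <- volume$affine %*% M
  resample_index_map(volume, M, out_dim, rep(iso_spacing, 3), out_affine,
                     outside = outside)
}

#' Window and normalize Hounsfield intensities
#'
#' Clips to `hu_window = c(lo, hi)` then rescales linearly to `[0, 1]`.
#'
#' @param volume a [ct_volume()].
#' @param hu_window length-2 numeric, `lo < hi`; default `c(-20, 80)`.
#' @return A [ct_volume()] with values in `[0, 1]`.
#' @export
window_hu <- function(volume, hu_window = c(-20, 80)) {
  stopifnot(inherits(volume, "ct_volume"))
  lo <- hu_window[1]; hi <- hu_window[2]
  if (!(lo < hi)) stop_asym("window", "hu_window must satisfy lo < hi")
  v <- pmin(pmax(volume$voxels, lo), hi)
  out <- volume
  out$voxels <- (v - lo) / (hi - lo)
  out
}

# Flip along the left-right (first, after reorientation) voxel axis, keeping
# grid and affine: the mirror about the grid's x-centre. Any offset between
# the grid centre and the true mid-sagittal plane is absorbed by the
# subsequent rigid registration.
mirror_lr <- function(volume) {
  out <- volume
  out$voxels <- volume$voxels[rev(seq_len(dim(volume$voxels)[1])), , ,
                              drop = FALSE]
  out
}
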