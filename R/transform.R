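# Six-parameter rigid transforms: three rotations (degrees, applied as
# Rz %*% Ry %*% Rx) and three translations (mm), acting in world space about a
# stated centre of rotation.

#' Rigid (6 degree-of-freedom) transform
#'
#' @param rotations numeric length-3, rotations about the world x, y, z axes
#'   in degrees (applied in the order Rx, then Ry, then Rz).
#' @param translations numeric length-3, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0)) {
  rotations <- as.numeric(rotations); translations <- as.numeric(translations)
  if (length(rotations) != 3 || length(translations) != 3 ||
      any(!is.finite(c(rotations, translations))))
    stop_asym("transform", "a rigid transform has exactly 6 finite parameters")
  structure(list(rotations = rotations, translations = translations),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %.3f %.3f %.3f | trans (mm): %.3f %.3f %.3f\n",
              x$rotations[1], x$rotations[2], x$rotations[3],
              x$translations[1], x$translations[2], x$translations[3]))
  invisible(x)
}

is_identity_transform <- function(x, tol = 0) {
  all(abs(c(x$rotations, x$translations)) <= tol)
}

rotation_matrix3 <- function(rot_deg) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# 4x4 world-space matrix of the transform about `center` (mm)
rt_matrix <- function(transform, center = c(0, 0, 0)) {
  R <- rotation_matrix3(transform$rotations)
  t <- transform$translations + center - R %*% center
  rbind(cbind(R, t), c(0, 0, 0, 1))
}

# Recover the 6 parameters from a rigid 4x4 world matrix about `center`.
rt_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
    stop_asym("transform", "matrix is not a proper rigid transform")
  # Euler extraction for Rz Ry Rx
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[1, 2], R[2, 2])
    rz <- 0
  }
  rot <- c(rx, ry, rz) * 180 / pi
  t <- M[1:3, 4] - center + R %*% center
  rigid_transform(rot, as.numeric(t))
}

# Matrix square root of a rigid 4x4 map: half the rotation (axis-angle) and
# the translation solving (I + R_half) t_half = t, so H %*% H == M.
rigid_sqrt <- function(M) {
  R <- M[1:3, 1:3]
  ca <- (sum(diag(R)) - 1) / 2
  ang <- acos(pmin(pmax(ca, -1), 1))
  if (ang < 1e-12) {
    Rh <- diag(3)
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
    a <- ang / 2
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    Rh <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  }
  th <- solve(diag(3) + Rh, M[1:3, 4])
  rbind(cbind(Rh, th), c(0, 0, 0, 1))
}

# world-center of a volume's grid (mm): mean of the two opposite corners
grid_center_world <- function(volume) {
  dm <- dim(volume$voxels)
  corners <- rbind(c(0, 0, 0), dm - 1)
  colMeans(voxel_to_world(volume$affine, corners))
}

# Resample `volume` moved by `transform` (about `center`) onto its own grid:
# I_out(x) = I_in(T^{-1} x).
apply_rigid <- function(volume, transform, center = NULL, outside = -1000,
                        nearest = FALSE) {
  center <- center %||% grid_center_world(volume)
  Tm <- rt_matrix(transform, center)
  A <- volume$affine
  M <- solve(A) %*% solve(Tm) %*% A
  resample_index_map(volume, M, dim(volume$voxels), volume$spacing, A,
                     outside = outside, nearest = nearest)
}

#' Apply a known rigid misalignment to a volume
#'
#' Resamples the volume under the transform with trilinear interpolation,
#' for constructing registration problems with a known answer. The identity
#' transform short-circuits to an exact copy.
#'
#' @param volume a [ct_volume()].
#' @param transform a [rigid_transform()].
#' @param outside fill value (HU) for voxels mapped outside the grid.
#' @return The misaligned [ct_volume()] on the same grid.
#' @export
apply_misalignment <- function(volume, transform, outside = -1000) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!inherits(transform, "rigid_transform"))
    stop_asym("transform", "transform must be a rigid_transform (6 DOF)")
  if (is_identity_transform(transform)) return(volume)
  apply_rigid(volume, transform, outside = outside)
}
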