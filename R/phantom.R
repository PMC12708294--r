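# Synthetic head CT phantom: nested ellipsoids (skull shell, brain,
# mirrored ventricles) with an optional hypodense ellipsoidal lesion and
# i.i.d. Gaussian HU noise. Ground truth is known exactly, so every stage of
# the asymmetry pipeline is testable without real data.

#' Specification of a synthetic head CT phantom
#'
#' The head is modelled as nested ellipsoids centred on the world origin:
#' a brain ellipsoid (`brain_semiaxes`, mm), a skull shell of thickness
#' `skull_thickness` around it, and a pair of left-right mirrored ventricles
#' at CSF attenuation. An optional ellipsoidal lesion lowers brain HU by
#' `lesion_hu_drop` inside one hemisphere. The mid-sagittal plane is x = 0
#' (RAS+ world coordinates); voxel indexing is 0-based.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param skull_hu,brain_hu,csf_hu,background_hu tissue attenuations (HU).
#' @param noise_sd standard deviation of additive Gaussian noise (HU, >= 0).
#' @param brain_semiaxes brain ellipsoid semi-axes (mm).
#' @param skull_thickness skull shell thickness (mm).
#' @param lesion_center world-mm centre of the lesion, or `NULL` for none.
#' @param lesion_radii lesion ellipsoid semi-axes (mm, > 0).
#' @param lesion_hu_drop HU decrease inside the lesion.
#' @param misalignment optional [rigid_transform()] applied to the finished
#'   phantom (creates a known registration problem).
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 112, 80),
                         voxel_spacing = c(2, 2, 2),
                         skull_hu = 700, brain_hu = 35, csf_hu = 8,
                         background_hu = -1000, noise_sd = 2,
                         brain_semiaxes = c(70, 90, 65), skull_thickness = 6,
                         lesion_center = NULL, lesion_radii = NULL,
                         lesion_hu_drop = 15, misalignment = NULL, seed = 1L) {
  hu <- c(skull_hu, brain_hu, csf_hu, background_hu, lesion_hu_drop)
  if (any(!is.finite(hu))) stop_asym("phantom", "all HU fields must be finite")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_asym("phantom", "noise_sd must be >= 0")
  if (any(brain_semiaxes <= 0) || skull_thickness <= 0)
    stop_asym("phantom", "geometry parameters must be positive")
  if (xor(is.null(lesion_center), is.null(lesion_radii)))
    stop_asym("phantom", "lesion_center and lesion_radii must be given together")
  if (!is.null(lesion_radii)) {
    if (any(lesion_radii <= 0)) stop_asym("phantom", "lesion radii must be > 0")
    if (abs(lesion_center[1]) < lesion_radii[1])
      stop_asym("phantom",
                "invariant violated: lesion must lie entirely within one hemisphere")
    # sufficient condition for the lesion ellipsoid to sit inside the brain
    if (sum(((abs(lesion_center) + lesion_radii) / brain_semiaxes)^2) > 1)
      stop_asym("phantom",
                "invariant violated: lesion must lie entirely within the brain ellipsoid")
  }
  if (!is.null(misalignment) && !inherits(misalignment, "rigid_transform"))
    stop_asym("phantom", "misalignment must be a rigid_transform")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 skull_hu = skull_hu, brain_hu = brain_hu, csf_hu = csf_hu,
                 background_hu = background_hu, noise_sd = noise_sd,
                 brain_semiaxes = brain_semiaxes,
                 skull_thickness = skull_thickness,
                 lesion_center = lesion_center, lesion_radii = lesion_radii,
                 lesion_hu_drop = lesion_hu_drop, misalignment = misalignment,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Lesion geometry for a target volume
#'
#' Convenience helper: a spherical lesion of volume `target_ml` placed in the
#' left (or right) hemisphere, 2 mm lateral of the mid-sagittal plane.
#'
#' @param target_ml target lesion volume in mL.
#' @param side `"left"` or `"right"`.
#' @return List with `center` (mm) and `radii` (mm) for [phantom_spec()].
#' @export
lesion_for_volume <- function(target_ml, side = c("left", "right")) {
  side <- match.arg(side)
  r <- (3 * target_ml * 1000 / (4 * pi))^(1 / 3)
  sx <- if (side == "left") -1 else 1
  list(center = c(sx * (r + 2), 0, 0), radii = c(r, r, r))
}

# squared normalized ellipsoid coordinate field over the grid (recycled sums)
ellipsoid_field <- function(xs, ys, zs, center, semiaxes, dm) {
  x2 <- ((xs - center[1]) / semiaxes[1])^2
  y2 <- ((ys - center[2]) / semiaxes[2])^2
  z2 <- ((zs - center[3]) / semiaxes[3])^2
  array(x2, dm) + rep(y2, each = dm[1]) + rep(z2, each = dm[1] * dm[2])
}

build_phantom_arrays <- function(spec) {
  dm <- spec$grid_shape; sp <- spec$voxel_spacing
  xs <- (seq_len(dm[1]) - 1 - (dm[1] - 1) / 2) * sp[1]
  ys <- (seq_len(dm[2]) - 1 - (dm[2] - 1) / 2) * sp[2]
  zs <- (seq_len(dm[3]) - 1 - (dm[3] - 1) / 2) * sp[3]
  brain <- ellipsoid_field(xs, ys, zs, c(0, 0, 0), spec$brain_semiaxes, dm) <= 1
  outer_sk <- ellipsoid_field(xs, ys, zs, c(0, 0, 0),
                              spec$brain_semiaxes + spec$skull_thickness, dm) <= 1
  hu <- array(spec$background_hu, dm)
  hu[outer_sk] <- spec$skull_hu
  hu[brain] <- spec$brain_hu
  # mirrored lateral ventricles (symmetric about x = 0 by construction)
  vent_ax <- pmin(c(8, 20, 10), spec$brain_semiaxes / 4)
  for (sx in c(-1, 1)) {
    vent <- ellipsoid_field(xs, ys, zs, c(sx * 12, 10, 8) *
                              min(1, spec$brain_semiaxes[1] / 70),
                            vent_ax, dm) <= 1
    hu[vent & brain] <- spec$csf_hu
  }
  lesion <- array(FALSE, dm)
  if (!is.null(spec$lesion_radii)) {
    les <- ellipsoid_field(xs, ys, zs, spec$lesion_center, spec$lesion_radii,
                           dm) <= 1
    lesion <- les & brain
    hu[lesion] <- hu[lesion] - spec$lesion_hu_drop
  }
  list(hu = hu, brain = brain, lesion = lesion)
}

#' Generate a head CT phantom with known ground truth
#'
#' Builds the phantom of [phantom_spec()]: background, skull shell, brain with
#' mirrored ventricles, optional hypodense lesion, plus additive Gaussian
#' noise. The same spec and seed always reproduce the identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]), `lesion_mask` (a
#'   [lesion_mask()] holding the exact ground truth), `brain_mask` (logical
#'   array) and `truth_ml` (analytic mask volume in mL).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  parts <- build_phantom_arrays(spec)
  hu <- parts$hu
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       array(rnorm(length(hu), 0, spec$noise_sd), dim(hu)))
    hu <- hu + noise
  }
  vol <- ct_volume(hu, spacing = spec$voxel_spacing)
  if (!is.null(spec$misalignment) &&
      !is_identity_transform(spec$misalignment)) {
    vol <- apply_misalignment(vol, spec$misalignment,
                              outside = spec$background_hu)
  }
  mask <- lesion_mask(parts$lesion, spacing = spec$voxel_spacing,
                      provenance = list(source = "phantom ground truth",
                                        seed = spec$seed))
  list(volume = vol, lesion_mask = mask, brain_mask = parts$brain,
       truth_ml = sum(parts$lesion) * prod(spec$voxel_spacing) / 1000)
}

#' Generate a symmetric reference template
#'
#' A perfectly left-right symmetric, noise-free head volume at 1 mm isotropic
#' spacing, serving as a stand-in standard-space template for rigid spatial
#' standardization. The spec must not request a lesion, noise or misalignment.
#'
#' @param spec a [phantom_spec()]; its spacing is forced to 1 mm isotropic.
#' @param grid_shape optional override of the template grid (voxels).
#' @return A [ct_volume()] that equals its own left-right mirror exactly.
#' @export
make_template <- function(spec = phantom_spec(noise_sd = 0), grid_shape = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$lesion_radii))
    stop_asym("template", "a template spec must not contain a lesion")
  if (!is.null(spec$misalignment) &&
      !is_identity_transform(spec$misalignment))
    stop_asym("template", "a template spec must not be misaligned")
  if (spec$noise_sd != 0)
    stop_asym("template", "a template spec must have noise_sd = 0")
  spec$voxel_spacing <- c(1, 1, 1)
  if (!is.null(grid_shape)) {
    spec$grid_shape <- as.integer(grid_shape)
  } else {
    # rescale the default grid to cover the head at 1 mm
    ext <- 2 * (spec$brain_semiaxes + spec$skull_thickness) + 16
    spec$grid_shape <- as.integer(ceiling(ext))
  }
  parts <- build_phantom_arrays(spec)
  ct_volume(parts$hu, spacing = c(1, 1, 1))
}
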