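# Shared fixtures: small phantoms keep the suite inside the runtime budget.
# Imaging tests run at 2 mm spacing with iso_spacing = 2 (a stated
# scale-down; the 1 mm contracts are tested on small grids where pinned).

test_config <- function(...) segmentation_config(iso_spacing = 2, ...)

small_head_spec <- function(...) {
  # half-size head: fast skull strip / registration exercises
  phantom_spec(grid_shape = c(56, 64, 48), voxel_spacing = c(2, 2, 2),
               brain_semiaxes = c(35, 45, 32), skull_thickness = 6, ...)
}

lesion_phantom <- function(target_ml, seed = 1, noise_sd = 3,
                           side = "left") {
  les <- lesion_for_volume(target_ml, side = side)
  make_phantom(phantom_spec(lesion_center = les$center,
                            lesion_radii = les$radii,
                            noise_sd = noise_sd, seed = seed))
}

dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# residual parameters of (recovered o true): how far the composition is from
# the identity, as rotations (deg) and translations (mm)
recovery_residual <- function(recovered, true, center) {
  M <- asymstroke:::rt_matrix(recovered, center) %*%
    asymstroke:::rt_matrix(true, center)
  asymstroke:::rt_from_matrix(M, center)
}
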