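# phantom generator: analytic ground truth, determinism, template symmetry,
# misalignment contracts

test_that("ground-truth mask volume matches the analytic ellipsoid volume", {
  # spherical lesion, radius 16.8 mm -> (4/3) pi r^3 = 19.86 mL
  les <- lesion_for_volume(19.86)
  expect_equal(les$radii[1], 16.8, tolerance = 1e-3)
  ph <- lesion_phantom(19.86, seed = 1)
  analytic <- 4 / 3 * pi * prod(les$radii) / 1000
  expect_lt(abs(ph$truth_ml - analytic) / analytic, 0.02)
  expect_equal(lesion_volume_ml(ph$lesion_mask), ph$truth_ml)

  # radii >= 5 voxels across a few sizes
  for (ml in c(10, 30)) {
    p2 <- lesion_phantom(ml, seed = 2)
    expect_lt(abs(p2$truth_ml - ml) / ml, 0.02)
  }
})

test_that("no-lesion spec yields an empty mask", {
  ph <- make_phantom(phantom_spec(noise_sd = 1, seed = 3))
  expect_equal(sum(ph$lesion_mask$voxels), 0)
  expect_equal(lesion_volume_ml(ph$lesion_mask), 0)
})

test_that("seed contract: identical masks, different noise; bit-reproducible", {
  les <- lesion_for_volume(15)
  sp1 <- phantom_spec(lesion_center = les$center, lesion_radii = les$radii,
                      noise_sd = 3, seed = 1)
  sp2 <- phantom_spec(lesion_center = les$center, lesion_radii = les$radii,
                      noise_sd = 3, seed = 2)
  a <- make_phantom(sp1); b <- make_phantom(sp2)
  expect_identical(a$lesion_mask$voxels, b$lesion_mask$voxels)
  expect_gt(max(abs(a$volume$voxels - b$volume$voxels)), 0)
  expect_identical(make_phantom(sp1)$volume$voxels, a$volume$voxels)
})

test_that("invalid lesions are rejected naming the invariant", {
  expect_error(phantom_spec(lesion_center = c(5, 0, 0),
                            lesion_radii = c(10, 10, 10)),
               "hemisphere")
  expect_error(phantom_spec(lesion_center = c(-69, 0, 0),
                            lesion_radii = c(10, 10, 10)),
               "within the brain")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(lesion_center = c(-20, 0, 0),
                            lesion_radii = c(10, -1, 10)),
               "radii")
})

test_that("template is exactly mirror-symmetric, 1 mm, deterministic", {
  tpl <- make_template(small_head_spec(noise_sd = 0))
  expect_equal(tpl$spacing, c(1, 1, 1))
  flipped <- tpl$voxels[rev(seq_len(dim(tpl$voxels)[1])), , , drop = FALSE]
  expect_identical(tpl$voxels, flipped)
  tpl2 <- make_template(small_head_spec(noise_sd = 0))
  expect_identical(tpl$voxels, tpl2$voxels)
})

test_that("template rejects lesion, noise and misalignment specs", {
  les <- lesion_for_volume(10)
  expect_error(make_template(small_head_spec(
    noise_sd = 0, lesion_center = les$center, lesion_radii = les$radii)),
    "lesion")
  expect_error(make_template(small_head_spec(noise_sd = 2)), "noise")
  expect_error(make_template(small_head_spec(
    noise_sd = 0, misalignment = rigid_transform(c(1, 0, 0), c(0, 0, 0)))),
    "misaligned")
})

test_that("apply_misalignment: identity short-circuit and rigid validation", {
  ph <- make_phantom(small_head_spec(noise_sd = 0))
  out <- apply_misalignment(ph$volume, rigid_transform())
  expect_identical(out$voxels, ph$volume$voxels)
  expect_error(apply_misalignment(ph$volume, list(rot = 1)), "rigid")
})

test_that("translation round trip returns close to the original", {
  ph <- make_phantom(small_head_spec(noise_sd = 0))
  fwd <- apply_misalignment(ph$volume, rigid_transform(c(0, 0, 0), c(4, 0, 0)))
  back <- apply_misalignment(fwd, rigid_transform(c(0, 0, 0), c(-4, 0, 0)))
  # interpolation round-trip error must stay below a plausible noise floor
  expect_lt(mean(abs(back$voxels - ph$volume$voxels)), 3)
})

test_that("rotation preserves the brain-mask volume within 1%", {
  # sphere-symmetric head: rotation about z leaves the geometry invariant,
  # so only interpolation can change the soft-tissue voxel count
  ph <- make_phantom(phantom_spec(noise_sd = 0,
                                  brain_semiaxes = c(60, 60, 60)))
  rot <- apply_misalignment(ph$volume, rigid_transform(c(0, 0, 5), c(0, 0, 0)))
  v0 <- sum(ph$volume$voxels > -200)   # head-tissue voxels
  v1 <- sum(rot$voxels > -200)
  expect_lt(abs(v1 - v0) / v0, 0.01)
})
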