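test_that("phantom specs validate geometry and containment", {
  expect_silent(phantom_spec())
  expect_error(phantom_spec(stem_radius = -1), "positive")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  # a stem wider than the canal violates containment
  expect_error(phantom_spec(stem_radius = 26, stem_radius_tip = 26),
               "geometry error")
  # so does a steep implant tilt driving the stem into the cortex
  expect_error(phantom_spec(implant_pose = rigid_transform(
    rotation_about_axis(c(1, 0, 0), 40))), "geometry error")
})

test_that("reference geometry is watertight with the requested dimensions", {
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  expect_true(mesh_is_watertight(geom$bone_mesh))
  expect_true(mesh_is_watertight(geom$implant_mesh))
  expect_true(all(c("posterior_edge", "distal_notch") %in%
                    rownames(geom$landmarks)))
  # bounding-box oracle on the parametric mesh
  spec70 <- quick_spec(plate_width = 70)
  bb <- mesh_bbox(build_phantom_geometry(spec70)$implant_mesh)
  expect_equal(unname(bb[2, 1] - bb[1, 1]), 70, tolerance = 1e-6)
  # deterministic construction
  g2 <- build_phantom_geometry(spec)
  expect_identical(geom$implant_mesh$vertices, g2$implant_mesh$vertices)
})

test_that("acquisition presets encode the sampling geometry", {
  mars <- mars_preset()
  expect_equal(mars$in_plane_spacing, 180 / 224)
  expect_equal(round(mars$in_plane_spacing, 4), 0.8036)
  expect_equal(mars$slice_thickness_mm, 3)
  ref <- reference_preset()
  expect_equal(ref$in_plane_spacing, 200 / 512)
  expect_error(acquisition_preset(0, 224, 3), "preset error")
})

test_that("voxelization samples the intensity model deterministically", {
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  preset <- quick_preset()
  v1 <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh,
                             identity_transform(), preset, spec)
  expect_equal(v1$spacing, c(180 / 64, 180 / 64, 3))
  # metal/void above the stem center, gelatin far out
  expect_equal(sample_volume(v1, c(0, 0, 1)), 0)
  expect_equal(sample_volume(v1, c(60, 0, -60)), 200)
  # bit-identical repeat, including the Rician noise path
  specn <- phantom_spec(noise_sigma = 4, seed = 3L)
  n1 <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh,
                             identity_transform(), preset, specn, acq_index = 2)
  n2 <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh,
                             identity_transform(), preset, specn, acq_index = 2)
  expect_identical(n1$data, n2$data)
  expect_gt(min(n1$data), 0) # Rician magnitudes are positive
  # a relocation pushing the phantom out of the grid is caught
  far <- rigid_transform(translation = c(120, 0, 0))
  expect_error(voxelize_acquisition(geom$bone_mesh, geom$implant_mesh, far,
                                    preset, spec), "field-of-view")
})

test_that("noise-free volumes agree after resampling back through the relocation", {
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  preset <- quick_preset()
  reloc <- rigid_transform(rotation_about_axis(c(0, 0, 1), 15), c(3, -4, 2))
  v0 <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh,
                             identity_transform(), preset, spec)
  v1 <- voxelize_acquisition(geom$bone_mesh, geom$implant_mesh, reloc,
                             preset, spec)
  # probe interior points away from tissue boundaries
  probes <- rbind(c(55, 0, -60), c(0, -50, -40), c(40, 30, -90),
                  c(0, 21.5, -55))
  a <- sample_volume(v0, probes)
  b <- sample_volume(v1, transform_points(reloc, probes))
  expect_lt(max(abs(a - b)), 25) # partial-volume tolerance
})

test_that("series generation respects the zero-motion guarantee and bounds", {
  spec <- quick_spec()
  preset <- quick_preset()
  series <- generate_series(spec, preset, n_acq = 4, seed = 13)
  man <- series$manifest
  expect_length(series$volumes, 4)
  poses <- lapply(man$acquisitions, function(a) a$implant_in_bone)
  for (p in poses[-1]) expect_identical(p, poses[[1]]) # bitwise constancy
  expect_error(generate_series(spec, preset, n_acq = 2, seed = 1),
               "series error")

  # relocation magnitude bound over many seeded draws
  series2 <- generate_series(spec, quick_preset(32), n_acq = 50, seed = 17,
                             max_rotation_deg = 25,
                             subsamples = c(1L, 1L, 1L))
  for (a in series2$manifest$acquisitions) {
    expect_lte(rotation_angle_deg(a$relocation$R), 25 + 2 * 5 + 1e-6)
    z_axis_roll <- abs(atan2(a$relocation$R[2, 1], a$relocation$R[1, 1])) * 180 / pi
    expect_lte(z_axis_roll, 25 + 5 + 1e-6)
  }
})

test_that("injected migrations accumulate between consecutive acquisitions", {
  spec <- quick_spec()
  preset <- quick_preset(32)
  inj <- migration_record(t_dp = 1.0)
  series <- generate_series(spec, preset, n_acq = 4, seed = 19,
                            injected_migration = inj,
                            subsamples = c(1L, 1L, 1L))
  man <- series$manifest
  M <- compose_6dof(inj, man$frame)
  for (i in 2:4) {
    expected <- compose_transforms(M, man$acquisitions[[i - 1]]$implant_in_bone)
    expect_transform_equal(man$acquisitions[[i]]$implant_in_bone, expected,
                           1e-12)
  }
  # an all-zero injection is exactly the zero-motion series
  zero <- generate_series(spec, preset, n_acq = 3, seed = 19,
                          injected_migration = migration_record(),
                          subsamples = c(1L, 1L, 1L))
  none <- generate_series(spec, preset, n_acq = 3, seed = 19,
                          subsamples = c(1L, 1L, 1L))
  expect_identical(zero$manifest$acquisitions[[3]]$implant_in_bone,
                   none$manifest$acquisitions[[3]]$implant_in_bone)
  expect_identical(zero$volumes[[2]]$data, none$volumes[[2]]$data)
})
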