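test_that("global alignment recovers rigid displacements of an asymmetric mesh", {
  set.seed(81)
  m <- asymmetric_mesh(3)
  expect_transform_equal(global_align(m, m), identity_transform(), 1e-6)

  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(8, -5, 3))
  moved <- transform_mesh(tr, m)
  est <- global_align(m, moved)
  err <- compose_transforms(invert_transform(tr), est)
  expect_lt(rotation_angle_deg(err$R), 0.5)
  expect_lt(sqrt(sum(err$t^2)), 0.5)
})

test_that("shapes with degenerate inertia are rejected as ambiguous", {
  sphere <- extract_surface(ball_mask(10), smooth_sigma = 0.8)
  expect_error(global_align(sphere, sphere), "ambiguous-alignment")
})

test_that("ICP refines to exact poses on noise-free meshes with monotone RMS", {
  set.seed(91)
  m <- asymmetric_mesh(2)
  self <- icp_refine(m, m, identity_transform())
  expect_lt(self$rms, 1e-9)
  expect_transform_equal(self$transform, identity_transform(), 1e-6)

  tr <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 2), c(1, -0.5, 0.7))
  moved <- transform_mesh(tr, m)
  init <- global_align(m, moved)
  res <- icp_refine(m, moved, init)
  err <- compose_transforms(invert_transform(tr), res$transform)
  expect_lt(rotation_angle_deg(err$R), 0.05)
  expect_lt(sqrt(sum(err$t^2)), 0.05)
  expect_true(all(diff(res$rms_history) <= 1e-9))
})

test_that("non-convergence is flagged, not raised", {
  m <- asymmetric_mesh(4)
  res <- icp_refine(m, transform_mesh(rigid_transform(translation = c(4, 0, 0)),
                                      m),
                    identity_transform(), max_iter = 2L)
  expect_false(res$converged)
})

test_that("landmark registration is a Procrustes fit with name matching", {
  lm <- rbind(posterior_edge = c(10, -20, 3), distal_notch = c(0, 0, -40),
              anterior_edge = c(0, 20, 3), lateral_corner = c(35, 20, 0))
  expect_transform_equal(landmark_register(lm, lm)$transform,
                         identity_transform(), 1e-9)

  set.seed(101)
  tr <- random_transform()
  moved <- transform_points(tr, lm)
  rownames(moved) <- rownames(lm)
  res <- landmark_register(lm, moved[sample(nrow(lm)), ])
  expect_transform_equal(res$transform, tr, 1e-9)
  expect_equal(res$method, "landmark")

  expect_error(landmark_register(lm[1:2, ], lm[1:2, ]),
               "degenerate-configuration")
  mismatched <- lm; rownames(mismatched)[1] <- "other"
  expect_error(landmark_register(lm, mismatched), "degenerate-configuration")
})

test_that("register_acquisition wires the three strategies correctly", {
  set.seed(111)
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  refs <- list(bone = geom$bone_mesh, implant = geom$implant_mesh)
  lm <- geom$landmarks

  # self-registration (the MMRI-W acquisition-1 case) gives identity
  res <- register_acquisition(geom$bone_mesh, geom$implant_mesh, refs,
                              method = "mmri-w")
  expect_transform_equal(res$bone$transform, identity_transform(), 1e-5)
  expect_transform_equal(res$implant$transform, identity_transform(), 1e-5)

  expect_error(register_acquisition(geom$bone_mesh, geom$implant_mesh, refs,
                                    method = "mmri-m"),
               "configuration error")

  res_m <- register_acquisition(geom$bone_mesh, geom$implant_mesh, refs,
                                method = "mmri-m",
                                landmarks = list(model = lm, seg = lm))
  expect_equal(res_m$implant$method, "landmark")
  expect_transform_equal(res_m$implant$transform, identity_transform(), 1e-5)
})

test_that("registration is equivariant under rigid relocation of the acquisition", {
  set.seed(121)
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  reloc <- rigid_transform(rotation_about_axis(c(0, 0, 1), 18) %*%
                             rotation_about_axis(c(1, 0, 0), 4),
                           c(3, -2, 5))
  moved_bone <- transform_mesh(reloc, geom$bone_mesh)
  moved_imp <- transform_mesh(reloc, geom$implant_mesh)
  res <- register_acquisition(moved_bone, moved_imp,
                              list(bone = geom$bone_mesh,
                                   implant = geom$implant_mesh),
                              method = "mmri-a")
  for (part in res) {
    err <- compose_transforms(invert_transform(reloc), part$transform)
    expect_lt(rotation_angle_deg(err$R), 0.06)
    expect_lt(sqrt(sum(err$t^2)), 0.06)
  }
})
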