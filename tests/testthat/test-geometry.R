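test_that("transform composition and inversion match the homogeneous-matrix oracle", {
  expect_transform_equal(compose_transforms(identity_transform(),
                                            identity_transform()),
                         identity_transform(), 1e-15)
  t1 <- rigid_transform(translation = c(1, 0, 0))
  t2 <- rigid_transform(translation = c(0, 2, 0))
  expect_equal(compose_transforms(t1, t2)$t, c(1, 2, 0))
  expect_equal(invert_transform(rigid_transform(translation = c(1, 2, 3)))$t,
               c(-1, -2, -3))

  set.seed(11)
  for (i in 1:200) {
    a <- random_transform(); b <- random_transform()
    oracle <- from_homogeneous(as_homogeneous(a) %*% as_homogeneous(b))
    expect_transform_equal(compose_transforms(a, b), oracle, 1e-12)
    inv_oracle <- from_homogeneous(solve(as_homogeneous(a)))
    expect_transform_equal(invert_transform(a), inv_oracle, 1e-12)
    expect_transform_equal(compose_transforms(a, invert_transform(a)),
                           identity_transform(), 1e-12)
  }
})

test_that("transform invariants are enforced at construction", {
  bad_rot <- diag(3); bad_rot[1, 1] <- 1.001
  expect_error(rigid_transform(bad_rot), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl), "det")
  expect_error(compose_transforms(list(R = diag(3), t = 0:2),
                                  identity_transform()), "invalid-transform")
})

test_that("rigid Procrustes recovers exact transforms and rejects degenerate input", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1), 4, 3, byrow = TRUE)
  same <- procrustes_rigid_fit(pts, pts)
  expect_transform_equal(same$transform, identity_transform(), 1e-12)
  expect_lt(same$rms, 1e-12)

  shifted <- procrustes_rigid_fit(pts, sweep(pts, 2, c(1, 2, 3), "+"))
  expect_transform_equal(shifted$transform,
                         rigid_transform(translation = c(1, 2, 3)), 1e-12)

  set.seed(21)
  for (i in 1:1000) {
    src <- matrix(rnorm(30, sd = 20), 10, 3)
    tr <- random_transform()
    fit <- procrustes_rigid_fit(src, transform_points(tr, src))
    expect_transform_equal(fit$transform, tr, 1e-9)
    expect_lt(fit$rms, 1e-9)
  }

  expect_error(procrustes_rigid_fit(pts[1:2, ], pts[1:2, ]),
               "degenerate-configuration")
  line_pts <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(procrustes_rigid_fit(line_pts, line_pts),
               "degenerate-configuration")
})

test_that("Procrustes never returns a reflection, even for mirrored targets", {
  set.seed(31)
  for (i in 1:50) {
    src <- matrix(rnorm(30), 10, 3)
    mirrored <- src %*% diag(c(-1, 1, 1))
    fit <- procrustes_rigid_fit(src, mirrored)
    expect_gt(det(fit$transform$R), 0.999999)
  }
})

test_that("anatomical frames must be right-handed orthonormal", {
  expect_silent(anatomical_frame())
  expect_error(anatomical_frame(axis_ml = c(1, 0, 0)), "right-handed")
  expect_error(anatomical_frame(axis_ml = c(1, 1, 0) / sqrt(2),
                                axis_dp = c(1, 0, 0)), "orthonormal")
})

test_that("6-DOF decomposition matches its stated conventions", {
  fr <- anatomical_frame(origin = c(3, -2, 7))
  zero <- decompose_6dof(identity_transform(), fr)
  expect_equal(unlist(zero[1:6]), c(t_ml = 0, t_dp = 0, t_pa = 0,
                                    r_fe = 0, r_ei = 0, r_vv = 0))

  # pure translation along the ML axis
  tr <- rigid_transform(translation = 0.5 * fr$A[, 1])
  rec <- decompose_6dof(tr, fr)
  expect_equal(rec$t_ml, 0.5, tolerance = 1e-12)
  expect_equal(abs(rec$t_dp) + abs(rec$t_pa) + abs(rec$r_fe) +
                 abs(rec$r_ei) + abs(rec$r_vv), 0, tolerance = 1e-12)

  # pure rotation about the ML axis through the origin is flexion-extension
  R <- rotation_about_axis(fr$A[, 1], 2)
  rot <- rigid_transform(R, fr$origin - as.numeric(R %*% fr$origin))
  rec <- decompose_6dof(rot, fr)
  expect_equal(rec$r_fe, 2, tolerance = 1e-9)
  expect_lt(max(abs(c(rec$t_ml, rec$t_dp, rec$t_pa, rec$r_ei, rec$r_vv))), 1e-9)
})

test_that("compose/decompose round-trip is exact away from gimbal lock", {
  set.seed(41)
  for (i in 1:1000) {
    fr <- anatomical_frame(origin = rnorm(3, sd = 30))
    rec <- migration_record(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
                            runif(1, -89, 89), runif(1, -89, 89),
                            runif(1, -89, 89))
    back <- decompose_6dof(compose_6dof(rec, fr), fr)
    expect_lt(max(abs(unlist(back[1:6]) - unlist(rec[1:6]))), 1e-9)
  }
})

test_that("gimbal lock raises an explicit error", {
  fr <- anatomical_frame()
  R <- rotation_about_axis(fr$A[, 2], 90)
  expect_error(decompose_6dof(rigid_transform(R), fr), "gimbal-lock")
})

test_that("migration records validate their components", {
  expect_error(migration_record(t_ml = NaN), "finite")
  expect_error(migration_record(r_vv = 200), "180")
})

test_that("transforms serialize to self-describing JSON lists and back", {
  set.seed(51)
  tr <- random_transform()
  lst <- transform_to_list(tr, anatomical_frame())
  expect_match(lst$euler_convention, "ML->DP->PA")
  expect_transform_equal(transform_from_list(lst), tr, 1e-15)
})
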