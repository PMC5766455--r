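test_that("parametric primitives are watertight and sized as requested", {
  cyl <- cylinder_mesh(c(0, 0), 5, 5, -10, 10)
  expect_true(mesh_is_watertight(cyl))
  tube <- tube_mesh(c(0, 0), 10, 12, 6, 7, -20, 0)
  expect_true(mesh_is_watertight(tube))
  prism <- extrude_polygon(rbind(c(0, 0), c(4, 0), c(4, 3), c(2, 1), c(0, 3)),
                           0, 2)
  expect_true(mesh_is_watertight(prism))
  bb <- mesh_bbox(prism)
  expect_equal(unname(bb[2, ] - bb[1, ]), c(4, 3, 2))
})

test_that("cylinder surface area approaches the analytic value", {
  cyl <- cylinder_mesh(c(0, 0), 5, 5, 0, 20, n_theta = 96, n_z = 4)
  analytic <- 2 * pi * 5 * 20 + 2 * pi * 25
  expect_lt(abs(mesh_area(cyl) / analytic - 1), 0.01)
})

test_that("subdivision preserves geometry while refining edges", {
  m <- extrude_polygon(rbind(c(0, 0), c(30, 0), c(30, 20), c(0, 20)), 0, 5)
  s <- mesh_subdivide(m, 4)
  expect_true(mesh_is_watertight(s))
  expect_equal(mesh_area(s), mesh_area(m), tolerance = 1e-12)
  e <- rbind(s$faces[, 1:2], s$faces[, 2:3], s$faces[, c(3, 1)])
  elen <- sqrt(rowSums((s$vertices[e[, 1], ] - s$vertices[e[, 2], ])^2))
  expect_lte(max(elen), 4)
})

test_that("normal offsetting shifts a sphere radius by the offset", {
  s <- extract_surface(ball_mask(10), smooth_sigma = 0.8)
  ctr <- mesh_centroid(s)
  r0 <- mean(sqrt(rowSums(sweep(s$vertices, 2, ctr)^2)))
  for (d in c(-1, 2)) {
    so <- mesh_offset(s, d)
    r1 <- mean(sqrt(rowSums(sweep(so$vertices, 2, ctr)^2)))
    expect_equal(r1 - r0, d, tolerance = 0.1)
  }
})

test_that("transforming a mesh moves vertices rigidly", {
  set.seed(61)
  m <- asymmetric_mesh(8)
  tr <- random_transform()
  mt <- transform_mesh(tr, m)
  expect_equal(mt$vertices, transform_points(tr, m$vertices))
  expect_equal(mesh_area(mt), mesh_area(m), tolerance = 1e-9)
})
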