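# shared fixtures: random rigid transforms, small meshes, quick phantoms

random_transform <- function(max_angle = 180, max_trans = 10) {
  ax <- rnorm(3)
  rigid_transform(rotation_about_axis(ax, runif(1, -max_angle, max_angle)),
                  runif(3, -max_trans, max_trans))
}

# 4x4 homogeneous matrix oracle for transform algebra
as_homogeneous <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- tr$R
  m[1:3, 4] <- tr$t
  m
}

from_homogeneous <- function(m) rigid_transform(m[1:3, 1:3], m[1:3, 4])

# an asymmetric closed test mesh (box with unequal sides plus corner bump),
# subdivided so vertex-based alignment has something to hold on to
asymmetric_mesh <- function(edge = 4) {
  box <- extrude_polygon(rbind(c(-20, -8), c(20, -8), c(26, 2), c(8, 12),
                               c(-20, 12)), -5, 5)
  bump <- cylinder_mesh(c(12, -2), 3, 1.5, 5, 14, n_theta = 12, n_z = 6)
  mesh_subdivide(merge_meshes(box, bump), edge)
}

# small phantom + coarse preset for fast end-to-end runs
quick_spec <- function(...) phantom_spec(noise_sigma = 0, ...)

quick_preset <- function(matrix = 64) acquisition_preset(180, matrix, 3)

# digital ball mask
ball_mask <- function(r = 10, n = 2 * r + 5, spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  idx <- seq_len(n)
  arr <- array(FALSE, c(n, n, n))
  for (k in idx) for (j in idx) {
    arr[, j, k] <- (idx - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r^2
  }
  mmri_mask(arr, spacing)
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$R - b$R)), tol)
  expect_lt(max(abs(a$t - b$t)), tol)
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
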