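# brute-force Otsu oracle: scan all candidate cuts on the sample values,
# maximizing between-class variance; ties resolved to the plateau midpoint
otsu_oracle <- function(x, bins = 256L) {
  edges <- seq(min(x), max(x), length.out = bins + 1L)
  score <- function(cut) {
    a <- x[x < cut]; b <- x[x >= cut]
    if (!length(a) || !length(b)) return(-Inf)
    length(a) / length(x) * length(b) / length(x) * (mean(a) - mean(b))^2
  }
  sc <- vapply(edges[-1], score, numeric(1))
  best <- max(sc)
  mean(edges[-1][sc >= best - 1e-9 * max(abs(best), 1)])
}

test_that("profile thresholding matches the brute-force Otsu oracle", {
  vol <- mmri_volume(array(rep(c(100, 300), each = 32), c(8, 8, 1)))
  line <- profile_line(c(0, 0, 0), c(7, 7, 0), n = 64)
  win <- profile_threshold(vol, line)
  expect_equal(win$low, 200, tolerance = 2 * 200 / 256) # within one bin
  expect_equal(win$high, 300)

  # gelatin/cortical style boundary with a partial-volume ramp
  prof <- c(rep(200, 30), seq(200, 50, length.out = 8), rep(50, 30))
  vol2 <- mmri_volume(array(rep(prof, 4), c(length(prof), 4, 1)))
  line2 <- profile_line(c(0, 1, 0), c(length(prof) - 1, 1, 0), n = 128)
  win2 <- profile_threshold(vol2, line2)
  expect_gt(win2$low, 50)
  expect_lt(win2$low, 200)
  tt <- seq(0, 1, length.out = 128)
  samples <- sample_volume(vol2, outer(1 - tt, c(0, 1, 0)) +
                             outer(tt, c(length(prof) - 1, 1, 0)))
  expect_equal(win2$low, otsu_oracle(samples), tolerance = 1.5)
})

test_that("constant profiles raise a no-contrast error", {
  vol <- mmri_volume(array(150, c(8, 8, 2)))
  expect_error(profile_threshold(vol, profile_line(c(0, 0, 0), c(7, 7, 1))),
               "no-contrast")
})

test_that("region growing selects exactly the seeded connected component", {
  arr <- array(0, c(20, 20, 3))
  arr[2:6, 2:6, ] <- 100    # blob A
  arr[12:16, 12:16, ] <- 100 # blob B, disjoint
  vol <- mmri_volume(arr)
  grown <- region_grow(vol, c(50, 150), c(3, 3, 2))
  # oracle: connected-component labelling via iterative dilation in R
  expect_equal(sum(grown$data), 5 * 5 * 3)
  expect_true(all(which(grown$data, arr.ind = TRUE)[, 1] <= 6))

  uniform <- mmri_volume(array(100, c(5, 5, 5)))
  expect_equal(sum(region_grow(uniform, c(50, 150), c(1, 1, 1))$data), 125)

  expect_error(region_grow(vol, c(50, 150), c(10, 10, 2)), "seed error")
})

test_that("26- vs 6-connectivity differ across diagonal touches", {
  arr <- array(0, c(4, 4, 1))
  arr[1, 1, 1] <- 100; arr[2, 2, 1] <- 100
  vol <- mmri_volume(arr)
  expect_equal(sum(region_grow(vol, c(50, 150), c(1, 1, 1), 26)$data), 2)
  expect_equal(sum(region_grow(vol, c(50, 150), c(1, 1, 1), 6)$data), 1)
})

test_that("mask edits are exact set operations with bounds checking", {
  m <- mmri_mask(array(TRUE, c(5, 5, 5)))
  expect_equal(edit_mask(m)$data, m$data)
  erased <- edit_mask(m, erase = which(m$data, arr.ind = TRUE))
  expect_equal(sum(erased$data), 0)
  hole <- matrix(c(1, 1, 1, 2, 1, 1, 3, 1, 1, 1, 2, 1, 1, 3, 1), ncol = 3,
                 byrow = TRUE)
  refilled <- edit_mask(erased, fill = hole)
  expect_equal(sum(refilled$data), 5)
  expect_error(edit_mask(m, erase = matrix(c(9, 1, 1), 1)), "bounds error")
})

test_that("morphological closing fills holes, is idempotent and extensive", {
  # EBImage as the independent oracle for per-slice disk closing
  skip_if_not_installed("EBImage")
  set.seed(71)
  for (i in 1:20) {
    arr <- array(runif(20^3) < 0.4, c(20, 20, 20))
    m <- mmri_mask(arr)
    ours <- morph_close(m, 2, mode = "slice")
    # identical structuring element, independent dilate/erode machinery
    off <- mmri:::disk_offsets(2, "slice")
    kern <- matrix(0, 5, 5)
    kern[cbind(off[, 1] + 3, off[, 2] + 3)] <- 1
    oracle <- array(FALSE, dim(arr))
    for (k in 1:20) {
      # pad so border behaviour matches closing on the infinite grid
      sl <- matrix(0, 30, 30)
      sl[6:25, 6:25] <- arr[, , k]
      cl <- EBImage::closing(sl, kern)
      oracle[, , k] <- cl[6:25, 6:25] > 0.5
    }
    expect_equal(ours$data, oracle)
    expect_true(all(ours$data[arr]))                      # extensive
    expect_equal(morph_close(ours, 2, mode = "slice")$data, ours$data) # idempotent
  }
})

test_that("closing a solid cuboid changes nothing and fills interior holes", {
  arr <- array(FALSE, c(12, 12, 5))
  arr[3:10, 3:10, 2:4] <- TRUE
  solid <- mmri_mask(arr)
  expect_equal(morph_close(solid, 2)$data, solid$data)
  holed <- arr; holed[6, 6, 3] <- FALSE
  closed <- morph_close(mmri_mask(holed), 2)
  expect_true(closed$data[6, 6, 3])
  empty <- mmri_mask(array(FALSE, c(5, 5, 5)))
  expect_equal(sum(morph_close(empty, 1)$data), 0)
})

test_that("surface extraction produces closed, accurate iso-surfaces", {
  # single interior voxel: a topological sphere (V - E + F = 2)
  m1 <- mmri_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)))
  s1 <- extract_surface(m1)
  expect_true(mesh_is_watertight(s1))
  expect_equal(nrow(s1$vertices) - nrow(s1$faces) * 3 / 2 + nrow(s1$faces), 2)

  # digital ball r = 10: area within 5 % of the analytic sphere
  s <- extract_surface(ball_mask(10))
  expect_true(mesh_is_watertight(s))
  expect_lt(abs(mesh_area(s) / (4 * pi * 100) - 1), 0.05)

  expect_error(extract_surface(mmri_mask(array(FALSE, c(4, 4, 4)))),
               "empty-segmentation")
})

test_that("surface vertices stay within one voxel diagonal of the mask boundary", {
  m <- ball_mask(8, spacing = c(1, 2, 1))
  s <- extract_surface(m)
  idx <- which(m$data, arr.ind = TRUE)
  bnd <- idx[apply(idx, 1, function(v) {
    nb <- expand.grid(v[1] + (-1):1, v[2] + (-1):1, v[3] + (-1):1)
    nb <- nb[rowSums(abs(sweep(as.matrix(nb), 2, v))) == 1, ]
    nb <- nb[apply(nb, 1, function(u) all(u >= 1 & u <= dim(m$data))), ]
    !all(m$data[as.matrix(nb)])
  }), , drop = FALSE]
  bnd_world <- voxel_to_world(m, bnd)
  nn <- sqrt(rowSums((s$vertices -
    bnd_world[apply(s$vertices, 1, function(p)
      which.min(colSums((t(bnd_world) - p)^2))), ])^2))
  expect_lt(max(nn), sqrt(sum(m$spacing^2)))
})

test_that("sub-voxel refinement recovers a plane shifted off the voxel grid", {
  # plane at z = 10.7 mm in a 3 mm-slice grid: mask boundary is quantized,
  # refinement must recover the true interface position
  n <- c(24, 24, 12)
  z <- ((1:12) - 1) * 3
  arr <- array(0, n)
  for (k in 1:12) {
    frac <- pmin(pmax((10.7 - (z[k] - 1.5)) / 3, 0), 1) # coverage below plane
    arr[, , k] <- 200 * (1 - frac)
  }
  vol <- mmri_volume(arr, spacing = c(1, 1, 3))
  mask <- mask_like(vol, vol$data <= 25)
  mesh <- extract_surface(mask)
  top <- mesh$vertices[, 3] > 6 & abs(mesh$vertices[, 1] - 11) < 6 &
    abs(mesh$vertices[, 2] - 11) < 6
  ref <- refine_surface_subvoxel(mesh, vol, c(-25, 25))
  expect_lt(abs(mean(ref$vertices[top, 3]) - 10.7), 0.25)
})
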