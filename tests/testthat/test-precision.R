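test_that("zero-motion precision matches a brute-force two-pass oracle", {
  set.seed(161)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    tab <- as.data.frame(matrix(rnorm(n * 6, sd = 2), n, 6))
    names(tab) <- c("t_ml", "t_dp", "t_pa", "r_fe", "r_ei", "r_vv")
    summ <- zero_motion_precision(tab)
    for (d in names(tab)) {
      x <- tab[[d]]
      mu_o <- sum(x) / n
      sd_o <- sqrt(sum((x - mu_o)^2) / (n - 1))
      row <- summ[summ$dof == d, ]
      expect_equal(row$mu, mu_o, tolerance = 1e-12)
      expect_equal(row$sigma, sd_o, tolerance = 1e-12)
      expect_equal(row$ci95_low, mu_o - 1.96 * sd_o, tolerance = 1e-12)
      expect_equal(row$ci95_high, mu_o + 1.96 * sd_o, tolerance = 1e-12)
    }
  }
})

test_that("degenerate record tables are rejected", {
  tab <- data.frame(t_ml = 0, t_dp = 0, t_pa = 0, r_fe = 0, r_ei = 0, r_vv = 0)
  expect_error(zero_motion_precision(tab), "insufficient-data")
  expect_error(zero_motion_precision(data.frame(x = 1:5)), "insufficient-data")
  zeros <- tab[rep(1, 5), ]
  summ <- zero_motion_precision(zeros)
  expect_true(all(summ$mu == 0 & summ$sigma == 0 &
                    summ$ci95_low == 0 & summ$ci95_high == 0))
})

test_that("golden-standard flagging follows the CI-containment rule", {
  mk <- function(mu, sigma) {
    base <- c(-1.5, -0.5, 0.5, 1.5)
    tab <- data.frame(t_ml = 0, t_dp = 0, t_pa = 0, r_fe = 0, r_ei = 0,
                      r_vv = 0)[rep(1, 4), ]
    tab$t_ml <- mu + if (sigma > 0) sigma * base / stats::sd(base) else 0
    tab
  }
  # mu 0.128, sigma 0.584 translation: CI (-1.017, 1.273), outside +-0.5
  cg <- compare_to_golden(zero_motion_precision(mk(0.128, 0.584)))
  expect_false(cg$within[cg$dof == "t_ml"])
  expect_equal(cg$ci95_low[cg$dof == "t_ml"], 0.128 - 1.96 * 0.584,
               tolerance = 1e-9)
  # mu 0, sigma 0.2 translation: CI +-0.392 within +-0.5
  cg2 <- compare_to_golden(zero_motion_precision(mk(0, 0.2)))
  expect_true(cg2$within[cg2$dof == "t_ml"])
  # all-zero within
  zeros <- mk(0, 0); zeros$t_ml <- 0
  expect_true(all(compare_to_golden(zero_motion_precision(zeros))$within))
})

test_that("distance maps follow rigid-body kinematics", {
  m <- asymmetric_mesh(5)
  expect_equal(max(distance_map(identity_transform(), m)), 0)
  expect_equal(unique(round(distance_map(
    rigid_transform(translation = c(1, 0, 0)), m), 12)), 1)

  # pure rotation: displacement = 2 r sin(theta/2); vertex 50 mm from axis
  probe <- surface_mesh(rbind(c(50, 0, 0), c(0, 50, 0), c(0, 0, 50)),
                        matrix(c(1L, 2L, 3L), 1))
  R <- rotation_about_axis(c(0, 0, 1), 2)
  dm <- distance_map(rigid_transform(R), probe)
  expect_equal(dm[1], 2 * 50 * sin(pi / 180), tolerance = 1e-9)
  expect_equal(dm[2], 2 * 50 * sin(pi / 180), tolerance = 1e-9)
  expect_equal(dm[3], 0, tolerance = 1e-9)
  # proportional to distance from the axis
  two <- surface_mesh(rbind(c(10, 0, 0), c(20, 0, 0), c(0, 0, 1)),
                      matrix(c(1L, 2L, 3L), 1))
  dm2 <- distance_map(rigid_transform(R), two)
  expect_equal(dm2[2] / dm2[1], 2, tolerance = 1e-9)
})

test_that("presentation rounding is half-away-from-zero at 3 decimals", {
  expect_equal(round_half_away(-0.0325), -0.033)
  expect_equal(round_half_away(0.0325), 0.033)
  expect_equal(round_half_away(1.0004), 1.000)
  expect_equal(round_half_away(-1.6575), -1.658)
})

test_that("report bundles are deterministic and carry the summary row", {
  tab <- phantom_study_pairs("MMRI-M")
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  spec <- quick_spec()
  geom <- build_phantom_geometry(spec)
  f1 <- write_report(tab, out1, method = "mmri-m",
                     implant_mesh = geom$implant_mesh, frame = geom$frame)
  f2 <- write_report(tab, out2, method = "mmri-m",
                     implant_mesh = geom$implant_mesh, frame = geom$frame)
  expect_identical(readLines(f1$table), readLines(f2$table))
  lines <- readLines(f1$table)
  expect_match(lines[length(lines)], "^mu\\(sigma\\)")
  expect_match(lines[length(lines)], "0.128 \\(0.584\\)")
  expect_true(file.exists(f1$boxplot))
  expect_true(file.exists(f1$distance_map))
  # PLY round-trips the displacement field
  ply <- read_mesh(f1$distance_map)
  expect_false(is.null(attr(ply, "scalars")$displacement_mm))
  expect_error(write_report(tab[0, ], out1), "insufficient-data")
})

test_that("per-method sigma extremes match the min/max over DOF sigmas", {
  tab <- phantom_study_pairs()
  for (m in unique(tab$method)) {
    summ <- zero_motion_precision(tab[tab$method == m, ], method = m)
    tr <- summ$sigma[summ$kind == "translation"]
    ro <- summ$sigma[summ$kind == "rotation"]
    expect_equal(range(tr), c(min(tr), max(tr)))
    expect_equal(range(ro), c(min(ro), max(ro)))
    expect_true(all(summ$ci95_low <= summ$mu & summ$mu <= summ$ci95_high))
  }
})
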