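# points whose sample covariance (n-1) is exactly the identity
identity_cov_points <- function() {
  p <- rbind(diag(3), -diag(3))
  p * sqrt(5 / 2)  # cov of this 6-point set is (2/5) I before scaling
}

test_that("constructed identity-covariance points give the closed-form volume", {
  p <- identity_cov_points()
  expect_equal(unname(cov(p)), diag(3))
  e <- fit_ellipsoid(p, sd_multiplier = 2, npts = 20)
  expect_equal(e$analytic_volume, (4 / 3) * pi * 8, tolerance = 1e-12)
  expect_equal(round(e$analytic_volume, 3), 33.510)
  expect_lt(e$hull_volume, e$analytic_volume)
  expect_lt(abs(e$hull_volume - e$analytic_volume) / e$analytic_volume, 0.10)
  expect_false(e$degenerate)
})

test_that("mesh hull volume matches hand-computed inscribed polyhedra", {
  p <- identity_cov_points()
  # npts = 3, sd = 1: triangular bipyramid, V = 2 * (1/3) * A_triangle * 1
  e3 <- fit_ellipsoid(p, sd_multiplier = 1, npts = 3)
  expect_equal(e3$hull_volume, 2 / 3 * (3 / 2) * sin(2 * pi / 3),
               tolerance = 1e-12)
  # npts = 4: square prism (rings at z = +/- 1/2, r = cos(30 deg)) + 2 caps
  e4 <- fit_ellipsoid(p, sd_multiplier = 1, npts = 4)
  r <- cos(pi / 6)
  prism <- 2 * r^2 * 1
  cap <- (1 / 3) * 2 * r^2 * 0.5
  expect_equal(e4$hull_volume, prism + 2 * cap, tolerance = 1e-12)
})

test_that("mesh hull volume agrees with an independent triangulated-surface oracle", {
  set.seed(7)
  pts <- matrix(rnorm(600), ncol = 3) %*% diag(c(3, 1, 0.5)) +
    matrix(c(10, -5, 2000), 200, 3, byrow = TRUE)
  for (npts in c(5, 8, 20)) {
    e <- fit_ellipsoid(pts, sd_multiplier = 2, npts = npts)
    expect_equal(e$hull_volume, oracle_mesh_volume(e$mesh, npts),
                 tolerance = 1e-10)
  }
  # surface facets support the whole mesh: the triangulated solid IS the hull
  e <- fit_ellipsoid(pts, sd_multiplier = 2, npts = 8)
  ring1 <- 1L + seq_len(8)
  expect_true(plane_supports(e$mesh, 1L, ring1[1], ring1[2]))
  expect_true(plane_supports(e$mesh, ring1[1], ring1[2], ring1[2] + 8L))
})

test_that("hull volume increases with npts and converges to the closed form", {
  set.seed(11)
  pts <- matrix(rnorm(300, sd = 2), ncol = 3)
  vols <- vapply(c(10, 20, 40, 80), function(np)
    fit_ellipsoid(pts, npts = np)$hull_volume, numeric(1))
  expect_true(all(diff(vols) > 0))
  analytic <- fit_ellipsoid(pts, npts = 10)$analytic_volume
  expect_true(all(vols < analytic))
  expect_lt((analytic - vols[4]) / analytic, 0.01)
})

test_that("volumes are invariant under rotation and translation", {
  set.seed(21)
  pts <- matrix(rnorm(450), ncol = 3) %*% diag(c(2, 0.7, 0.1))
  R <- rotation_matrix(0.3, -1.1, 2.2)
  moved <- pts %*% t(R) + matrix(c(500, -200, 1300), nrow(pts), 3, byrow = TRUE)
  e0 <- fit_ellipsoid(pts)
  e1 <- fit_ellipsoid(moved)
  expect_equal(e1$hull_volume, e0$hull_volume, tolerance = 1e-9)
  expect_equal(e1$analytic_volume, e0$analytic_volume, tolerance = 1e-9)
})

test_that("volume scales as sd^3 and degenerate clouds are flagged, not errors", {
  set.seed(5)
  pts <- matrix(rnorm(150), ncol = 3)
  v1 <- fit_ellipsoid(pts, sd_multiplier = 1)
  v2 <- fit_ellipsoid(pts, sd_multiplier = 2)
  expect_equal(v2$hull_volume, 8 * v1$hull_volume, tolerance = 1e-12)
  expect_equal(v2$analytic_volume, 8 * v1$analytic_volume, tolerance = 1e-12)

  same <- matrix(5, 10, 3)
  e <- fit_ellipsoid(same)
  expect_true(e$degenerate)
  expect_equal(e$hull_volume, 0)
  expect_equal(e$analytic_volume, 0)
  # coplanar points: rank 2, still degenerate in 3-D
  flat <- cbind(matrix(rnorm(40), ncol = 2), 0)
  expect_true(fit_ellipsoid(flat)$degenerate)
  expect_error(fit_ellipsoid(matrix(1, 1, 3)), "at least 2")
})

test_that("per-run volumes over a run set summarize correctly", {
  rs <- generate_runset(tiny_config(n_runs = 3, n_frames = 50, seed = 2,
                                    noise_sd = 1, jitter = 1))
  ev <- ellipsoid_volumes(rs)
  expect_equal(nrow(ev$volumes), 3 * 2)
  expect_true(all(ev$volumes$hull_volume_mm3 > 0))
  # scaling one run's positions by k about a fixed point scales volumes by k^3
  k <- 1.7
  rs2 <- rs
  rs2$runs[[2]]$xyz <- (rs2$runs[[2]]$xyz - 100) * k + 100
  ev2 <- ellipsoid_volumes(rs2)
  r2 <- ev$volumes$run_id == 2
  expect_equal(ev2$volumes$hull_volume_mm3[r2],
               k^3 * ev$volumes$hull_volume_mm3[r2], tolerance = 1e-9)

  # identical runs: per-joint SD of volumes exactly 0
  det <- generate_runset(tiny_config(n_runs = 4, n_frames = 50, seed = 2,
                                     noise_sd = 1, shared_noise = TRUE))
  evd <- ellipsoid_volumes(det)
  expect_true(all(evd$summary$sd == 0))
})

test_that("isotropic Gaussian clouds recover the unit-sphere scaled volume", {
  vols <- vapply(1:50, function(s) {
    set.seed(s)
    fit_ellipsoid(matrix(rnorm(3e4), ncol = 3))$analytic_volume
  }, numeric(1))
  expect_true(all(abs(vols - 33.510) / 33.510 < 0.05))
})

test_that("coverage_fraction matches closed forms and a numeric chi-square oracle", {
  expect_equal(coverage_fraction(2, 2), 1 - exp(-2), tolerance = 1e-12)
  expect_equal(coverage_fraction(2, 1), 0.9545, tolerance = 1e-4)
  # independent numeric integration of the chi-square(3) density up to 4
  dens3 <- function(u) u^(1 / 2) * exp(-u / 2) / (2^(3 / 2) * gamma(3 / 2))
  oracle <- integrate(dens3, 0, 4, rel.tol = 1e-10)$value
  expect_equal(coverage_fraction(2, 3), oracle, tolerance = 1e-8)
  expect_equal(round(coverage_fraction(2, 3), 4), 0.7385)
  expect_error(coverage_fraction(2, 4), "dim")
  expect_error(coverage_fraction(0, 2))
})

test_that("the empirical mass inside the 2-SD ellipsoid matches the 3-D value", {
  set.seed(31)
  pts <- matrix(rnorm(3 * 2e5), ncol = 3)
  e <- fit_ellipsoid(pts, sd_multiplier = 2)
  S_inv <- solve(e$covariance)
  d <- sweep(pts, 2, e$center)
  maha2 <- rowSums((d %*% S_inv) * d)
  frac <- mean(maha2 <= 4)
  expect_lt(abs(frac - coverage_fraction(2, 3)), 0.01)
  # and it is NOT the 2-D figure often quoted for 2-SD ellipsoids
  expect_gt(abs(frac - coverage_fraction(2, 2)), 0.10)
})
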