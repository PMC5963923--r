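test_that("tissue generation is deterministic under a fixed seed", {
  sp <- small_tissue_spec(seed = 7)
  a <- generate_tissue_image(sp)
  b <- generate_tissue_image(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
})

test_that("zero gap fraction yields an empty truth table and no detections", {
  sp <- tissue_spec(n_cells = 20, field_size = 80, scale = 0.5,
                    gap_area_fraction = 0, n_gaps = 0, noise_sd = 0,
                    seed = 3)
  sc <- generate_tissue_image(sp)
  expect_equal(nrow(sc$truth), 0)
  # background is 0.2, walls 0.6: nothing below a sub-background cut
  lab <- segment_separations(sc$image, 0.2, "dark_gap", min_area = 0.5)
  expect_equal(max(lab), 0)
})

test_that("strongly concentrated gap orientations center on mu", {
  sc <- generate_tissue_image(field_tissue_spec(seed = 11, kappa = 50,
                                                n_gaps = 40))
  expect_equal(nrow(sc$truth), 40)
  s <- axial_summary(sc$truth$theta_deg)
  expect_lt(acute_diff(s$mean, 90), 3)
})

test_that("generated gaps are recovered by segmentation with matched areas", {
  sc <- generate_tissue_image(small_tissue_spec(seed = 23, n_gaps = 5))
  lab <- segment_separations(sc$image, 0.1, "dark_gap", min_area = 2)
  regs <- measure_regions(lab)
  expect_equal(nrow(regs), 5)
  # match regions to truth by centroid and compare areas and angles
  for (g in seq_len(nrow(sc$truth))) {
    d2 <- (regs$centroid_x_um - sc$truth$centroid_x_um[g])^2 +
          (regs$centroid_y_um - sc$truth$centroid_y_um[g])^2
    j <- which.min(d2)
    expect_lt(sqrt(d2[j]), 2)
    expect_lt(abs(regs$area_um2[j] - sc$truth$area_um2[g]) /
                sc$truth$area_um2[g], 0.1)
    expect_lt(acute_diff(regs$theta_G_deg[j], sc$truth$theta_deg[g]), 5)
  }
})

test_that("infeasible gap requests fail loudly", {
  sp <- small_tissue_spec(seed = 5)
  sp$n_gaps <- 500L   # far more gaps than interfaces
  expect_error(generate_tissue_image(sp), "infeasible")
  expect_error(tissue_spec(gap_area_fraction = 0.6), "0.5")
  expect_error(tissue_spec(n_cells = 3), ">= 4")
})

test_that("axial von Mises sampler converges to the A(kappa) resultant", {
  set.seed(1)
  for (kap in c(0.5, 2, 10)) {
    th <- sample_axial_vonmises(1e5, 37, kap)
    expect_lt(abs(axial_summary(th)$R - besselI(kap, 1) / besselI(kap, 0)),
              0.02)
  }
  # kappa = 0: rotation-invariant (uniform) orientations
  set.seed(2)
  th0 <- sample_axial_vonmises(1e5, 90, 0)
  expect_lt(axial_summary(th0)$R, 0.02)
  expect_true(all(th0 >= 0 & th0 < 180))
})

test_that("fibril scenes carry their assigned orientation and order", {
  m <- grid_mask(2, 1, 64)
  sc <- generate_fibril_scene(m, orientations = c(0, 45), order = 1,
                              period = 8, seed = 2)
  meas <- nematic_tensor_roi(sc$image, sc$mask)
  expect_lt(acute_diff(meas$theta_M_deg[1], 0), 2)
  expect_lt(acute_diff(meas$theta_M_deg[2], 45), 2)
  expect_true(all(meas$anisotropy > 0.9))

  # order 0: near-isotropic textures across seeds
  for (sd in 1:5) {
    sc0 <- generate_fibril_scene(grid_mask(1, 1, 64), orientations = 30,
                                 order = 0, period = 8, seed = sd)
    expect_lt(nematic_tensor_roi(sc0$image, sc0$mask)$anisotropy, 0.05)
  }

  # determinism
  s1 <- generate_fibril_scene(m, c(10, 20), order = 0.5, seed = 9)
  s2 <- generate_fibril_scene(m, c(10, 20), order = 0.5, seed = 9)
  expect_identical(s1$image$pixels, s2$image$pixels)

  expect_warning(generate_fibril_scene(m, c(190, 20), seed = 1),
                 "normalized")
})

test_that("ablation scenes interpolate between uniform and circumferential", {
  # full response: every acute angle exactly 90
  s1 <- generate_ablation_scene(50, response = 1, seed = 4)
  expect_equal(acute_angle_to_ablation(s1), rep(90, 50), tolerance = 1e-9)

  # no response: uniform on [0, 90], mean ~45, sd ~26
  s0 <- generate_ablation_scene(1e4, response = 0, seed = 5)
  a <- acute_angle_to_ablation(s0)
  expect_lt(abs(mean(a) - 45), 1)
  expect_lt(abs(sd(a) - 90 / sqrt(12)), 1)

  # intermediate response skews toward 90
  sh <- generate_ablation_scene(2000, response = 0.5, seed = 6)
  ah <- acute_angle_to_ablation(sh)
  expect_gt(mean(ah), 55)
  expect_lt(skewness(ah), -0.2)
})

test_that("force-curve models match their closed-form stiffness", {
  # exact line: slope recovered to float precision
  cv <- generate_force_curve("linear", true_slope = 3, n_points = 50)
  fit <- apparent_stiffness(cv)
  expect_equal(fit$k, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # convex power law: fitted deep-window slope exceeds the secant slope
  cvp <- generate_force_curve("power_law", true_slope = 2, exponent = 1.5,
                              max_depth = 1, n_points = 400)
  expect_true(all(diff(diff(cvp$F_uN)) > -1e-12))  # convex
  fitp <- apparent_stiffness(cvp)
  expect_gt(fitp$k, max(cvp$F_uN) / max(cvp$Z_um))

  # noise-free curves are non-decreasing
  expect_true(all(diff(cvp$F_uN) >= 0))
})

test_that("noisy linear curves recover the slope within 5% across seeds", {
  k <- vapply(1:100, function(sd) {
    cv <- generate_force_curve("linear_plus_noise", true_slope = 40,
                               max_depth = 1.5, n_points = 200,
                               noise_sd = 0.6, seed = sd)  # 1% of F_max
    apparent_stiffness(cv)$k
  }, numeric(1))
  # Monte-Carlo recovery: unbiased mean and the bulk of individual
  # estimates within 5% of the true slope
  expect_lt(abs(mean(k) - 40) / 40, 0.05)
  expect_gt(mean(abs(k - 40) / 40 < 0.05), 0.9)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(generate_ablation_scene(10, 0.5, seed = 77))
  invisible(generate_force_curve("linear_plus_noise", seed = 78,
                                 noise_sd = 1))
  after <- runif(1)
  expect_identical(before, after)
})
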