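test_that("nematic tensor recovers analytic grating orientations", {
  m <- grid_mask(1, 1, 64)
  # horizontal fibrils: intensity varies along rows only
  sc <- generate_fibril_scene(m, orientations = 0, order = 1, period = 8,
                              seed = 1)
  meas <- nematic_tensor_roi(sc$image, sc$mask)
  expect_lt(acute_diff(meas$theta_M_deg, 0), 2)
  expect_gt(meas$anisotropy, 0.9)

  # gratings across the angular range, including the 45-degree case
  for (th in c(30, 45, 60, 90, 120, 170)) {
    sct <- generate_fibril_scene(m, orientations = th, order = 1,
                                 period = 8, seed = 1)
    mt <- nematic_tensor_roi(sct$image, sct$mask)
    expect_lt(acute_diff(mt$theta_M_deg, th), 2)
  }

  # uniform ROI: no orientation signal
  u <- image2d(matrix(0.5, 66, 66), 1)
  mu <- nematic_tensor_roi(u, m)
  expect_true(mu$degenerate)
  expect_equal(mu$anisotropy, 0)
})

test_that("nematic orientation shifts exactly 90 degrees under rot90", {
  m <- grid_mask(1, 1, 64)
  sc <- generate_fibril_scene(m, orientations = 25, order = 1, period = 8,
                              seed = 3)
  base <- nematic_tensor_roi(sc$image, sc$mask)
  rot <- nematic_tensor_roi(image2d(rot90ccw(sc$image$pixels), 1),
                            rot90ccw(sc$mask))
  expect_lt(acute_diff(rot$theta_M_deg, (base$theta_M_deg + 90) %% 180),
            1e-6)
  expect_equal(rot$anisotropy, base$anisotropy, tolerance = 1e-9)
})

test_that("anisotropy is bounded and intensity-rescaling invariant", {
  m <- grid_mask(1, 1, 48)
  for (ord in c(0, 0.3, 0.7, 1)) {
    sc <- generate_fibril_scene(m, orientations = 70, order = ord,
                                period = 8, seed = 5)
    meas <- nematic_tensor_roi(sc$image, sc$mask)
    expect_gte(meas$anisotropy, 0)
    expect_lte(meas$anisotropy, 1)
    # affine intensity rescale leaves the normalized tensor unchanged
    resc <- image2d(0.25 + 0.5 * sc$image$pixels, sc$image$scale)
    meas2 <- nematic_tensor_roi(resc, sc$mask)
    expect_equal(meas2$anisotropy, meas$anisotropy, tolerance = 1e-9)
    if (!meas$degenerate) {
      expect_lt(acute_diff(meas2$theta_M_deg, meas$theta_M_deg), 1e-6)
    }
  }
  expect_error(nematic_tensor_roi(image2d(matrix(1, 3, 3), 1),
                                  matrix(1L, 3, 3)), ">= 16")
})

test_that("population summary recovers per-cell ground truth", {
  m <- grid_mask(5, 4, 48)
  set.seed(8)
  truths <- sample_axial_vonmises(20, 90, 10)
  sc <- generate_fibril_scene(m, orientations = truths, order = 0.8,
                              period = 8, seed = 8)
  res <- measure_cells(sc$image, sc$mask)
  expect_equal(nrow(res$measurements), 20)
  expect_true(res$summary$weighted)
  expect_lt(acute_diff(res$summary$mean, 90), 5)

  # fully disordered scene: low population resultant
  sc0 <- generate_fibril_scene(grid_mask(10, 5, 32),
                               orientations = rep(90, 50), order = 0,
                               period = 8, seed = 9)
  res0 <- measure_cells(sc0$image, sc0$mask)
  expect_lt(res0$summary$R, 0.3)
})

test_that("acute angle to ablation follows the geometry", {
  # cell due east, vertical array: circumferential, 90 degrees
  scene <- list(center = c(0, 0),
                cells = data.frame(cell = 1:3,
                                   x_um = c(10, 10, 10 * cos(pi / 4)),
                                   y_um = c(0, 0, 10 * sin(pi / 4)),
                                   theta_M_deg = c(90, 0, 170)))
  a <- acute_angle_to_ablation(scene)
  expect_equal(a[1], 90)
  expect_equal(a[2], 0)
  expect_equal(a[3], 55)   # min(|170 - 45|, 180 - |170 - 45|)

  # axial invariance: theta and theta + 180 give the same score
  scene$cells$theta_M_deg <- c(270 %% 360, 180, 350) # same orientations
  a2 <- acute_angle_to_ablation(scene)
  expect_equal(a2, a, tolerance = 1e-9)

  # degenerate cells are skipped with a message
  scene$cells$theta_M_deg <- c(90, NA, 170)
  expect_message(a3 <- acute_angle_to_ablation(scene), "skipping")
  expect_length(a3, 2)

  bad <- list(center = c(0, 0),
              cells = data.frame(cell = 1, x_um = 0, y_um = 0,
                                 theta_M_deg = 10))
  expect_error(acute_angle_to_ablation(bad), "coincides")
})

test_that("skewness and its significance test match independent references", {
  # frozen reference (independent implementation of the same statistic)
  x <- c(2.091817, 2.835346, 1.837216, 1.64507, 3.079255, 1.753374,
         2.346005, 2.189486, 3.077414, 1.439221, 3.795584, 1.172598,
         2.452653, 2.258302, 1.088972, 2.595075, 1.523847, 0.812777,
         2.822125, 0.565804, 0.946676, 1.821892, 3.063791, 2.705759,
         2.068475, 0.404492, 1.130183, 1.336096, 0.78015, 0.301378,
         1.885733, 2.763792, 1.255784, 3.037802, 0.502663, 0.739157,
         1.857382, 1.173697, 2.611779, 2.328643)
  st <- skewness_test(x)
  expect_equal(st$skewness, 0.0510959803, tolerance = 1e-7)
  expect_equal(st$z, 0.1499695631, tolerance = 1e-6)
  expect_equal(st$p_value, 0.8807886287, tolerance = 1e-6)

  y <- c(-0.363054, -0.381738, -1.19584, 0.486972, -0.469402, 0.012494,
         0.480747, 0.446531, 0.665385, -0.098485, -0.423298, -0.079718,
         -1.687334, -1.447112, -1.3227, -0.997247, 0.399774, -0.905479,
         -0.378163, 1.299228, -0.356264, 0.737516, -0.933618, -0.205438,
         -0.950022)
  st2 <- skewness_test(y)
  expect_equal(st2$skewness, 0.1054675779, tolerance = 1e-7)
  expect_equal(st2$p_value, 0.7970510657, tolerance = 1e-6)

  expect_error(skewness_test(rnorm(5)), "n >= 8")
})

test_that("ablation response summary captures reorientation", {
  # t8 fully circumferential: mean 90, sd 0 (constant sample warns in
  # the comparison branch)
  t8 <- rep(90, 20)
  set.seed(12)
  t0 <- runif(20, 0, 90)
  suppressWarnings(s <- ablation_response_summary(t0, t8))
  expect_equal(s$t8$mean, 90)
  expect_equal(s$t8$sd, 0)

  # large uniform sample: symmetric, mean 45, non-significant skewness
  set.seed(13)
  u <- runif(1e4, 0, 90)
  su <- suppressWarnings(ablation_response_summary(u, rep(90, 20)))
  expect_lt(abs(su$t0$mean - 45), 1)
  expect_lt(abs(su$t0$skewness), 0.05)
  expect_gt(su$t0$skew_p, 0.05)

  # simulated reorientation (response 0.7): negative, significant skew
  sc <- generate_ablation_scene(100, response = 0.7, seed = 14,
                                timepoint = "t8")
  a8 <- acute_angle_to_ablation(sc)
  sc0 <- generate_ablation_scene(100, response = 0, seed = 15)
  a0 <- acute_angle_to_ablation(sc0)
  s2 <- ablation_response_summary(a0, a8)
  expect_lt(s2$t8$skewness, 0)
  expect_lt(s2$t8$skew_p, 0.05)
  expect_equal(sum(s2$t8$hist$count), 100)
})
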