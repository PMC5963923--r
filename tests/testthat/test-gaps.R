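test_that("max projection takes per-pixel maxima", {
  a <- image2d(matrix(0, 6, 6), 1)
  b <- image2d(matrix(runif(36), 6, 6), 1)
  expect_identical(max_project(list(b))$pixels, b$pixels)
  expect_identical(max_project(list(a, b))$pixels, b$pixels)

  # disjoint bright pixels are both retained at original intensity
  p1 <- matrix(0, 6, 6); p1[2, 2] <- 0.7
  p2 <- matrix(0, 6, 6); p2[5, 5] <- 0.4
  pr <- max_project(list(image2d(p1, 1), image2d(p2, 1)))$pixels
  expect_equal(pr[2, 2], 0.7)
  expect_equal(pr[5, 5], 0.4)
  expect_equal(sum(pr > 0), 2)

  expect_error(max_project(list()), "non-empty")
})

test_that("threshold segmentation selects by polarity and filters speckle", {
  px <- matrix(0.5, 40, 40)
  px[3:8, 3:8] <- 0.01       # 36 px
  px[20:27, 20:23] <- 0.01   # 32 px
  px[33:38, 30:36] <- 0.01   # 42 px
  px[15, 15] <- 0.01         # single-pixel speckle
  img <- image2d(px, 0.5)    # px area 0.25 um^2
  lab <- segment_separations(img, 0.1, "dark_gap", min_area = 2)
  expect_equal(max(lab), 3)

  # uniform image: nothing to segment at a strict interior threshold
  u <- image2d(matrix(0.5, 10, 10), 1)
  expect_equal(max(segment_separations(u, 0.5, "dark_gap")), 0)

  # bright polarity selects the opposite tail
  labb <- segment_separations(image2d(1 - px, 0.5), 0.9, "bright_stripe",
                              min_area = 2)
  expect_equal(max(labb), 3)

  expect_error(segment_separations(img, 2, "dark_gap"), "range")
})

test_that("components touching diagonally are one 8-connected region", {
  px <- matrix(1, 20, 20)
  for (i in 1:10) px[4 + i, 4 + i] <- 0   # pure diagonal chain
  lab <- segment_separations(image2d(px, 1), 0.5, "dark_gap", min_area = 1)
  expect_equal(max(lab), 1)
})

test_that("region measurement matches frozen second-moment examples", {
  # 100-pixel region at 0.5 um/px: area arithmetic
  px <- matrix(1, 30, 30); px[11:20, 11:20] <- 0
  regs <- measure_regions(segment_separations(image2d(px, 0.5), 0.5,
                                              "dark_gap"))
  expect_equal(regs$area_um2, 25)
  expect_true(regs$degenerate)      # square: isotropic moments
  expect_equal(regs$anisotropy, 0)

  # 21 x 5 horizontal rectangle: discrete-uniform second moments give
  # theta 0 and anisotropy (36.667 - 2)/(36.667 + 2)
  px2 <- matrix(1, 30, 40); px2[10:14, 10:30] <- 0
  regs2 <- measure_regions(segment_separations(image2d(px2, 1), 0.5,
                                               "dark_gap"))
  expect_equal(regs2$theta_G_deg, 0)
  expect_equal(regs2$anisotropy, (440 / 12 - 2) / (440 / 12 + 2),
               tolerance = 1e-12)
  expect_false(regs2$degenerate)

  # empty label map: empty table, not an error
  expect_equal(nrow(measure_regions(matrix(0L, 5, 5), scale = 1)), 0)
})

test_that("theta_G and anisotropy match brute-force moments on random blobs", {
  set.seed(17)
  for (rep in 1:12) {
    # random oriented elliptical blob
    nr <- 80
    th <- runif(1, 0, pi)
    a <- runif(1, 12, 22); b <- runif(1, 3, 8)
    cx <- runif(1, 30, 50); cy <- runif(1, 30, 50)
    px <- matrix(1, nr, nr)
    for (r in 1:nr) for (cc in 1:nr) {
      x <- cc - cx; y <- -(r - cy)
      u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
      if ((u / a)^2 + (v / b)^2 < 1) px[r, cc] <- 0
    }
    lab <- segment_separations(image2d(px, 1), 0.5, "dark_gap")
    regs <- measure_regions(lab)
    expect_equal(nrow(regs), 1)
    idx <- which(unclass(lab) == 1)
    bf <- brute_force_moments((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1)
    expect_lt(acute_diff(regs$theta_G_deg, bf$theta), 1e-8)
    expect_equal(regs$anisotropy, bf$anisotropy, tolerance = 1e-10)
  }
})

test_that("theta_G is equivariant under raster rotation", {
  # oriented bar rotated by construction through a range of angles
  for (phi in c(0, 20, 45, 70, 110, 155)) {
    nr <- 120
    px <- matrix(1, nr, nr)
    th <- phi * pi / 180
    for (r in 1:nr) for (cc in 1:nr) {
      x <- cc - 60; y <- -(r - 60)
      u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
      if (abs(u) < 25 && abs(v) < 4) px[r, cc] <- 0
    }
    regs <- measure_regions(segment_separations(image2d(px, 1), 0.5,
                                                "dark_gap"))
    expect_gt(regs$n_pixels, 100)
    expect_lt(acute_diff(regs$theta_G_deg, phi), 2)
  }
})

test_that("area is conserved between mask and region table", {
  sc <- generate_tissue_image(small_tissue_spec(seed = 19, n_gaps = 6))
  lab <- segment_separations(sc$image, 0.1, "dark_gap", min_area = 2)
  regs <- measure_regions(lab)
  expect_equal(sum(regs$area_um2),
               sum(unclass(lab) > 0) * sc$image$scale^2)
})

test_that("gap summary aggregates areas, fraction and orientation sample", {
  regs <- data.frame(
    label = 1:3, area_um2 = c(10, 20, 5),
    centroid_x_um = 0, centroid_y_um = 0,
    theta_G_deg = c(80, 100, NA), anisotropy = c(0.9, 0.5, 0),
    degenerate = c(FALSE, FALSE, TRUE), n_pixels = c(40, 80, 20)
  )
  s <- summarize_gaps(regs, field_area = 700, weight_mode = "anisotropy")
  expect_equal(s$total_gap_area, 35)           # degenerate counts in area
  expect_equal(s$gap_fraction, 5)
  expect_equal(length(s$orientations), 2)      # but not in orientations
  expect_equal(s$orientations$weights, c(0.9, 0.5))

  # empty input
  empty <- measure_regions(matrix(0L, 4, 4), scale = 1)
  s0 <- summarize_gaps(empty, field_area = 100)
  expect_equal(s0$total_gap_area, 0)
  expect_equal(s0$gap_fraction, 0)
  expect_equal(length(s0$orientations), 0)

  expect_error(summarize_gaps(regs, field_area = 0), "positive")
})
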