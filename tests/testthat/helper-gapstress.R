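# Shared fixture builders.  Everything is generated in code; no binary
# fixtures are stored.

# Small, fast tissue spec for segmentation round-trips.
small_tissue_spec <- function(seed = 7, n_gaps = 5, kappa = 0, mu = 90,
                              polarity = "dark_gap",
                              gap_area_fraction = 0.03) {
  tissue_spec(
    n_cells = 30, field_size = 120, scale = 0.5,
    gap_polarity = polarity, gap_area_fraction = gap_area_fraction,
    n_gaps = n_gaps, orientation_mean = mu,
    orientation_concentration = kappa, noise_sd = 0.02, seed = seed
  )
}

# Full-field tissue at half resolution (512 px, 0.7276 um/px): same
# 372.4 um field and ~138654 um^2 area as the default, four times faster.
field_tissue_spec <- function(seed, kappa, n_gaps = 40, mu = 90,
                              gap_area_fraction = 0.05) {
  tissue_spec(
    n_cells = 120, field_size = 372.4, scale = 0.7276,
    gap_polarity = "dark_gap", gap_area_fraction = gap_area_fraction,
    n_gaps = n_gaps, orientation_mean = mu,
    orientation_concentration = kappa, noise_sd = 0.02, seed = seed
  )
}

# Brute-force second moments of an explicit pixel list (independent of
# measure_regions): population covariance of (x = col, y = -row), eigen
# decomposition via R's eigen().
brute_force_moments <- function(rows, cols) {
  x <- cols
  y <- -rows
  n <- length(x)
  S <- matrix(c(
    mean(x^2) - mean(x)^2, mean(x * y) - mean(x) * mean(y),
    mean(x * y) - mean(x) * mean(y), mean(y^2) - mean(y)^2
  ), 2, 2)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  theta <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(theta = theta,
       anisotropy = (e$values[1] - e$values[2]) / sum(e$values))
}

# Independent axial-mean oracle: 0.01-degree grid search minimizing the
# weighted circular squared (chord) distance on the doubled circle.
grid_search_axial_mean <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  grid <- seq(0, 180 - 0.01, by = 0.01)
  loss <- vapply(grid, function(m) {
    sum(weights * (1 - cos(2 * (angles - m) * pi / 180)))
  }, numeric(1))
  grid[which.min(loss)]
}

# Acute axial difference helper mirroring the package's convention.
acute_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Rotate a matrix 90 degrees counter-clockwise (top-right -> top-left).
rot90ccw <- function(m) {
  out <- t(m)
  out[rev(seq_len(nrow(out))), , drop = FALSE]
}
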