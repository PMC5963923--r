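#' Sample axial orientations from a von Mises law
#'
#' Draws axial angles (degrees in \eqn{[0, 180)}) whose doubled angles
#' follow a von Mises distribution with mean direction \eqn{2\mu} and
#' concentration \eqn{\kappa} -- the standard construction for axial
#' data.  \eqn{\kappa = 0} gives the uniform axial distribution.
#'
#' Sampling uses the Best-Fisher (1979) rejection algorithm, vectorized
#' in batches.
#'
#' @param n number of draws.
#' @param mu axial mean orientation in degrees.
#' @param kappa concentration (>= 0).
#' @return Numeric vector of degrees in \eqn{[0, 180)}.
#' @export
sample_axial_vonmises <- function(n, mu, kappa) {
  if (kappa < 0) stopf("`kappa` must be non-negative")
  if (n == 0L) return(numeric(0))
  phi <- rvonmises(n, deg2rad(2 * mu), kappa)   # doubled angles
  normalize_axial(rad2deg(phi) / 2)
}

# Best-Fisher rejection sampler for von Mises(mu, kappa) on [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(64L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- stats::runif(m)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out <- c(out, theta[ok])
  }
  (out[seq_len(n)] + mu) %% (2 * pi)
}

#' Specification of a synthetic epidermis mosaic
#'
#' Parameters for [generate_tissue_image].  Defaults mirror a typical
#' confocal field: a 1024 x 1024 px projection at 0.3638 um/px, i.e. a
#' 372.4 x 372.4 um field of about 138654 um^2.
#'
#' @param n_cells number of cells in the mosaic (>= 4).
#' @param field_size side length of the square field in micrometres.
#' @param scale micrometres per pixel.
#' @param gap_polarity how separations are rendered: `"dark_gap"`
#'   (openings darker than background, as in cotyledons) or
#'   `"bright_stripe"` (thin bright stain-filled bands, as in stems).
#' @param gap_area_fraction fraction of the field area occupied by
#'   separations, in \[0, 0.5).
#' @param n_gaps number of separation regions to place.
#' @param orientation_mean mean axial orientation mu of the separations,
#'   degrees in \[0, 180).
#' @param orientation_concentration concentration kappa of the axial von
#'   Mises law (0 = uniform orientations).
#' @param noise_sd Gaussian intensity noise SD (image intensities are on
#'   \[0, 1\]).
#' @param wall_width_um rendered cell-wall width in micrometres.
#' @param seed integer seed; the same spec and seed give bit-identical
#'   output.
#' @return A list of class `tissue_spec`.
#' @export
tissue_spec <- function(n_cells = 120,
                        field_size = 372.4,
                        scale = 0.3638,
                        gap_polarity = c("dark_gap", "bright_stripe"),
                        gap_area_fraction = 0.05,
                        n_gaps = 40,
                        orientation_mean = 90,
                        orientation_concentration = 0,
                        noise_sd = 0.02,
                        wall_width_um = 1.2,
                        seed = 1L) {
  gap_polarity <- match.arg(gap_polarity)
  if (n_cells < 4) stopf("`n_cells` must be >= 4")
  if (gap_area_fraction < 0 || gap_area_fraction >= 0.5) {
    stopf("`gap_area_fraction` must lie in [0, 0.5)")
  }
  if (orientation_concentration < 0) stopf("`orientation_concentration` >= 0 required")
  structure(
    list(n_cells = as.integer(n_cells), field_size = field_size,
         scale = scale, gap_polarity = gap_polarity,
         gap_area_fraction = gap_area_fraction,
         n_gaps = as.integer(n_gaps),
         orientation_mean = normalize_axial(orientation_mean),
         orientation_concentration = orientation_concentration,
         noise_sd = noise_sd, wall_width_um = wall_width_um,
         seed = as.integer(seed)),
    class = "tissue_spec"
  )
}

#' Generate a synthetic epidermis image with known separation truth
#'
#' Builds a cell mosaic by seeded-region tessellation (Poisson-disk cell
#' centers, pixels assigned to the nearest center), renders cell walls,
#' and inserts cell-separation regions on cell-cell interfaces.  Each
#' separation's axial orientation is drawn from the axial von Mises law
#' of the spec and matched to the free interface whose own axial angle
#' (perpendicular to the line joining the two adjacent cell centers) is
#' closest; the region is rendered as an elongated patch along that
#' interface.  `"dark_gap"` patches are rendered below background
#' intensity, `"bright_stripe"` as thin high-intensity bands.
#'
#' Fixed intensity model: background (cell interior) 0.2, walls 0.6,
#' bright stripes 1.0, dark gaps 0.02, plus Gaussian noise, clipped to
#' \[0, 1\].
#'
#' @param spec a [tissue_spec].
#' @return A list of class `tissue_scene`:
#'   * `image` -- the rendered [image2d];
#'   * `cells` -- integer label raster of the cell ROIs (the mosaic);
#'   * `truth` -- data frame with one row per generated separation:
#'     `gap`, `centroid_x_um`, `centroid_y_um`, `area_um2`,
#'     `theta_deg` (axial orientation of the rendered patch).
#' @examples
#' \donttest{
#' sc <- generate_tissue_image(tissue_spec(n_cells = 30, field_size = 120,
#'   scale = 0.5, n_gaps = 8, gap_area_fraction = 0.04, seed = 7))
#' nrow(sc$truth)
#' }
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, generate_tissue_image_impl(spec))
}

generate_tissue_image_impl <- function(spec) {
  npx <- round(spec$field_size / spec$scale)
  sc <- spec$scale
  A_field <- (npx * sc)^2

  pts <- poisson_disk_points(spec$n_cells, npx * sc)

  # nearest / second-nearest cell center for every pixel center
  xs <- (seq_len(npx) - 0.5) * sc
  ys <- (npx - seq_len(npx) + 0.5) * sc   # row -> y (upward)
  X <- matrix(xs, npx, npx, byrow = TRUE)
  Y <- matrix(ys, npx, npx)
  d1 <- matrix(Inf, npx, npx); d2 <- d1
  i1 <- matrix(0L, npx, npx);  i2 <- i1
  for (k in seq_len(nrow(pts))) {
    d <- (X - pts[k, 1])^2 + (Y - pts[k, 2])^2
    closer <- d < d1
    d2[closer] <- d1[closer]; i2[closer] <- i1[closer]
    d1[closer] <- d[closer];  i1[closer] <- k
    mid <- !closer & d < d2
    d2[mid] <- d[mid]; i2[mid] <- k
  }
  wall <- (sqrt(d2) - sqrt(d1)) < spec$wall_width_um

  img <- matrix(0.2, npx, npx)
  img[wall] <- 0.6

  truth <- data.frame(gap = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), area_um2 = numeric(0),
                      theta_deg = numeric(0))

  if (spec$gap_area_fraction > 0 && spec$n_gaps > 0) {
    ifc <- interface_table(i1, i2, wall, X, Y, pts)
    # keep interfaces clear of the image border
    margin <- 0.1 * npx * sc
    ifc <- ifc[ifc$mx > margin & ifc$mx < npx * sc - margin &
               ifc$my > margin & ifc$my < npx * sc - margin, ]
    if (nrow(ifc) < spec$n_gaps) {
      stopf("infeasible gap request: %d gaps but only %d usable interfaces",
            spec$n_gaps, nrow(ifc))
    }
    A_gap <- spec$gap_area_fraction * A_field / spec$n_gaps
    gap_val <- if (spec$gap_polarity == "dark_gap") 0.02 else 1.0
    if (spec$gap_polarity == "dark_gap") {
      h_w <- max(sc, sqrt(A_gap / 4) / 2)      # aspect ~4:1
    } else {
      h_w <- max(sc, 1.5 * sc)                 # thin band ~3 px wide
    }
    h_l <- A_gap / (4 * h_w)
    target <- sample_axial_vonmises(spec$n_gaps, spec$orientation_mean,
                                    spec$orientation_concentration)
    occupied <- matrix(FALSE, npx, npx)
    used <- rep(FALSE, nrow(ifc))
    rows_painted <- vector("list", spec$n_gaps)
    placed <- 0L
    for (j in seq_len(spec$n_gaps)) {
      ord <- order(axial_difference(ifc$theta, target[j]) + ifelse(used, 1e6, 0))
      done <- FALSE
      for (cand in ord) {
        if (used[cand]) break
        sel <- rect_pixels(ifc$mx[cand], ifc$my[cand], ifc$theta[cand],
                           h_l, h_w, npx, sc)
        if (length(sel) == 0L) next
        # require clearance from previously painted separations
        if (any(occupied[neighborhood(sel, npx)])) next
        used[cand] <- TRUE
        occupied[sel] <- TRUE
        placed <- placed + 1L
        img[sel] <- gap_val
        rr <- (sel - 1L) %% npx + 1L
        ccol <- (sel - 1L) %/% npx + 1L
        truth <- rbind(truth, data.frame(
          gap = placed,
          centroid_x_um = mean(ccol - 0.5) * sc,
          centroid_y_um = (npx - mean(rr - 0.5)) * sc,
          area_um2 = length(sel) * sc^2,
          theta_deg = ifc$theta[cand]
        ))
        done <- TRUE
        break
      }
      if (!done) {
        stopf("infeasible gap placement: placed %d of %d separations without overlap",
              placed, spec$n_gaps)
      }
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(npx * npx, 0, spec$noise_sd), npx, npx)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(image = image2d(img, sc), cells = i1, truth = truth, spec = spec),
    class = "tissue_scene"
  )
}

# Poisson-disk (dart-throwing) points in a square of side L; the minimal
# distance is relaxed geometrically if the target count cannot be hit.
poisson_disk_points <- function(n, L) {
  rmin <- 0.62 * sqrt(L^2 / n)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    cand <- c(stats::runif(1, 0, L), stats::runif(1, 0, L))
    ok <- nrow(pts) == 0L ||
      min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= rmin^2
    if (ok) {
      pts <- rbind(pts, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 200L) {
        rmin <- rmin * 0.92
        tries <- 0L
      }
    }
  }
  unname(pts)
}

# Table of cell-cell interfaces: midpoint, pixel count, axial angle
# perpendicular to the line joining the two adjacent cell centers.
interface_table <- function(i1, i2, wall, X, Y, pts) {
  idx <- which(wall & i2 > 0L)
  a <- pmin(i1[idx], i2[idx])
  b <- pmax(i1[idx], i2[idx])
  key <- paste(a, b)
  sp <- split(seq_along(idx), key)
  out <- lapply(sp, function(ii) {
    if (length(ii) < 12L) return(NULL)      # skip tiny corner contacts
    px <- idx[ii]
    ka <- a[ii[1L]]; kb <- b[ii[1L]]
    dvec <- pts[kb, ] - pts[ka, ]
    data.frame(
      mx = mean(X[px]), my = mean(Y[px]), n_px = length(ii),
      theta = normalize_axial(rad2deg(atan2(dvec[2], dvec[1])) + 90)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mx = numeric(0), my = numeric(0), n_px = integer(0),
                      theta = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# Linear indices of pixels inside a rotated rectangle centred at
# (mx, my) um with axial angle theta, half-length h_l, half-width h_w.
rect_pixels <- function(mx, my, theta, h_l, h_w, npx, sc) {
  rad <- h_l + h_w
  c_lo <- max(1L, floor((mx - rad) / sc)); c_hi <- min(npx, ceiling((mx + rad) / sc))
  r_lo <- max(1L, floor((npx * sc - my - rad) / sc))
  r_hi <- min(npx, ceiling((npx * sc - my + rad) / sc))
  if (c_lo > c_hi || r_lo > r_hi) return(integer(0))
  rr <- r_lo:r_hi; ccol <- c_lo:c_hi
  x <- (matrix(ccol, length(rr), length(ccol), byrow = TRUE) - 0.5) * sc - mx
  y <- (npx - matrix(rr, length(rr), length(ccol)) + 0.5) * sc - my
  th <- deg2rad(theta)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  sel <- abs(u) < h_l & abs(v) < h_w
  row_idx <- matrix(rr, length(rr), length(ccol))[sel]
  col_idx <- matrix(ccol, length(rr), length(ccol), byrow = TRUE)[sel]
  (col_idx - 1L) * npx + row_idx
}

# Linear indices of `sel` plus their 8-neighborhood (clipped to bounds).
neighborhood <- function(sel, npx) {
  rr <- (sel - 1L) %% npx + 1L
  ccol <- (sel - 1L) %/% npx + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r2 <- rr + dr; c2 <- ccol + dc
    ok <- r2 >= 1L & r2 <= npx & c2 >= 1L & c2 <= npx
    out <- c(out, (c2[ok] - 1L) * npx + r2[ok])
  }
  unique(out)
}

#' Generate a fibrillar texture scene with known per-cell orientation
#'
#' Fills each cell of a label mask with a sinusoidal grating of the
#' cell's assigned orientation, blended with uniform pixel noise
#' according to a per-cell order parameter: 1 gives a pure grating
#' (perfect alignment), 0 pure noise (no orientational order).  This
#' emulates a cortical-microtubule surface signal with controllable
#' ground truth for the nematic-tensor quantification.
#'
#' @param roi_mask integer label matrix (0 = background) defining cells.
#' @param orientations per-cell axial orientation in degrees (recycled);
#'   values outside \[0, 180) are normalized with a warning.
#' @param order per-cell order parameter in \[0, 1\] (recycled).
#' @param period grating period in pixels.
#' @param scale micrometres per pixel of the emitted image.
#' @param seed integer seed.
#' @return A list of class `fibril_scene`: `image` ([image2d]), `mask`,
#'   and `truth` (data frame: `cell`, `theta_deg`, `order`).
#' @export
generate_fibril_scene <- function(roi_mask, orientations, order = 1,
                                  period = 8, scale = 0.5, seed = 1L) {
  cells <- sort(unique(roi_mask[roi_mask > 0L]))
  if (length(cells) == 0L) stopf("`roi_mask` has no labeled cells")
  if (any(orientations < 0 | orientations >= 180)) {
    warnf("orientations outside [0, 180) normalized into the axial range")
    orientations <- normalize_axial(orientations)
  }
  orientations <- rep_len(orientations, length(cells))
  order <- rep_len(order, length(cells))
  if (any(order < 0 | order > 1)) stopf("`order` must lie in [0, 1]")
  nr <- nrow(roi_mask); nc <- ncol(roi_mask)
  img <- with_seed(seed, {
    out <- matrix(stats::runif(nr * nc), nr, nc)  # background noise
    for (j in seq_along(cells)) {
      px <- which(roi_mask == cells[j])
      rr <- (px - 1L) %% nr + 1L
      ccol <- (px - 1L) %/% nr + 1L
      # coordinate along the grating normal (x = col, y = -row)
      th <- deg2rad(orientations[j] + 90)
      w <- ccol * cos(th) - rr * sin(th)
      grating <- 0.5 + 0.5 * sin(2 * pi * w / period)
      noise <- stats::runif(length(px))
      out[px] <- order[j] * grating + (1 - order[j]) * noise
    }
    out
  })
  structure(
    list(image = image2d(img, scale), mask = roi_mask,
         truth = data.frame(cell = cells, theta_deg = orientations,
                            order = order)),
    class = "fibril_scene"
  )
}

#' Build a rectangular grid of square cell ROIs
#'
#' Convenience mask generator: `nx` by `ny` square cells of `cell_px`
#' pixels separated by 1-px background gutters, labeled row-major.
#'
#' @param nx,ny grid dimensions.
#' @param cell_px cell side in pixels.
#' @return Integer label matrix.
#' @export
grid_mask <- function(nx, ny, cell_px = 64) {
  nr <- ny * (cell_px + 1L) + 1L
  nc <- nx * (cell_px + 1L) + 1L
  m <- matrix(0L, nr, nc)
  lab <- 0L
  for (gy in seq_len(ny)) for (gx in seq_len(nx)) {
    lab <- lab + 1L
    r0 <- (gy - 1L) * (cell_px + 1L) + 2L
    c0 <- (gx - 1L) * (cell_px + 1L) + 2L
    m[r0:(r0 + cell_px - 1L), c0:(c0 + cell_px - 1L)] <- lab
  }
  m
}

#' Generate an ablation scene with a controlled reorientation response
#'
#' Places `n_cells` cells on a ring around a central ablation point and
#' assigns each an axial orientation interpolating between uniform axial
#' random (`response = 0`, no reorientation) and exactly circumferential
#' (`response = 1`, full alignment with the tension rings around a
#' wound): the orientation is the circumferential direction plus the
#' perturbation \eqn{90\,\mathrm{sign}(u)\,|u|^{1/(1-\mathrm{response})}}
#' degrees with \eqn{u} uniform on \eqn{(-1, 1)}.  With `response = 0`
#' the acute angle to the radial direction is uniform on \[0, 90\]
#' (mean 45, SD about 26 degrees); intermediate responses pile
#' orientations smoothly toward circumferential, giving the
#' characteristic negative skew of the acute-angle distribution.
#'
#' @param n_cells number of surrounding cells (>= 1).
#' @param response reorientation strength in \[0, 1\].
#' @param seed integer seed.
#' @param ring_radius_um ring radius in micrometres.
#' @param timepoint label carried in the scene (e.g. `"t0"`, `"t8"`).
#' @return An object of class `ablation_scene`: `center` (c(x, y) um),
#'   `cells` (data frame: `cell`, `x_um`, `y_um`, `theta_M_deg`,
#'   `anisotropy`), `timepoint`.
#' @export
generate_ablation_scene <- function(n_cells, response, seed = 1L,
                                    ring_radius_um = 30, timepoint = "t0") {
  if (n_cells < 1L) stopf("`n_cells` must be >= 1")
  if (response < 0 || response > 1) stopf("`response` must lie in [0, 1]")
  cells <- with_seed(seed, {
    bearing <- stats::runif(n_cells, 0, 360)
    u <- stats::runif(n_cells, -1, 1)
    jitter <- if (response >= 1) {
      rep(0, n_cells)
    } else {
      90 * sign(u) * abs(u)^(1 / (1 - response))
    }
    data.frame(
      cell = seq_len(n_cells),
      x_um = ring_radius_um * cos(deg2rad(bearing)),
      y_um = ring_radius_um * sin(deg2rad(bearing)),
      theta_M_deg = normalize_axial(bearing + 90 + jitter),
      anisotropy = 1
    )
  })
  structure(
    list(center = c(0, 0), cells = cells, timepoint = timepoint),
    class = "ablation_scene"
  )
}

#' Generate a synthetic AFM force-indentation curve
#'
#' Samples an (indentation depth Z, force F) curve of known behavior for
#' validating [apparent_stiffness]: a pure line of slope `true_slope`, a
#' power law \eqn{F \propto Z^{\mathrm{exponent}}}, or a line plus
#' Gaussian force noise.
#'
#' @param model `"linear"`, `"power_law"`, or `"linear_plus_noise"`.
#' @param true_slope slope in N/m (equivalently uN/um).
#' @param exponent power-law exponent (used by `"power_law"`).
#' @param max_depth maximal indentation depth in micrometres.
#' @param n_points number of samples (>= 10).
#' @param noise_sd force noise SD in micronewtons (used by
#'   `"linear_plus_noise"`).
#' @param seed integer seed.
#' @return A [force_curve].
#' @export
generate_force_curve <- function(model = c("linear", "power_law",
                                           "linear_plus_noise"),
                                 true_slope = 40, exponent = 1.5,
                                 max_depth = 1.5, n_points = 200,
                                 noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  if (n_points < 10L) stopf("`n_points` must be >= 10")
  Z <- seq(0, max_depth, length.out = n_points)
  F <- switch(model,
    linear = true_slope * Z,
    power_law = true_slope * max_depth * (Z / max_depth)^exponent,
    linear_plus_noise = with_seed(seed,
      true_slope * Z + stats::rnorm(n_points, 0, noise_sd))
  )
  force_curve(Z, F, label = model)
}
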