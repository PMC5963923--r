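#' Per-cell fibril orientation and anisotropy from the nematic tensor
#'
#' Quantifies the dominant orientation `theta_M` and the degree of
#' alignment of a fibrillar texture (e.g. a cortical microtubule array)
#' inside each cell ROI, using the gradient-based nematic tensor: local
#' fibril direction is orthogonal to the intensity gradient, so with
#' per-pixel gradient \eqn{g = (g_x, g_y)} (central differences, edge
#' replication) each pixel contributes the tensor
#' \deqn{\begin{pmatrix} g_y^2 & -g_x g_y \\ -g_x g_y & g_x^2 \end{pmatrix},}
#' i.e. the outer product of the fibril direction weighted by
#' \eqn{|g|^2}.  The tensor is averaged over the ROI and normalized to
#' unit trace; `theta_M` is the axial angle of its leading eigenvector
#' and the anisotropy is the eigenvalue difference
#' \eqn{\lambda_1 - \lambda_2 \in [0, 1]} (0 isotropic, 1 perfectly
#' aligned).  ROI intensities are max-normalized first, which leaves the
#' trace-normalized tensor invariant to affine intensity rescaling.
#'
#' Uniform (zero-gradient) ROIs have no defined orientation and are
#' flagged `degenerate` with anisotropy 0.
#'
#' @param img an [image2d].
#' @param mask integer label matrix aligned with `img` (0 = background);
#'   each ROI must have at least 16 pixels.
#' @return A data frame of class `fibril_measurements`: `cell`,
#'   `theta_M_deg` (degrees in \eqn{[0,180)}, `NA` when degenerate),
#'   `anisotropy`, `n_pixels`, `degenerate`.
#' @examples
#' m <- grid_mask(1, 1, 48)
#' sc <- generate_fibril_scene(m, orientations = 30, order = 1, seed = 2)
#' nematic_tensor_roi(sc$image, sc$mask)
#' @export
nematic_tensor_roi <- function(img, mask) {
  stopifnot(inherits(img, "image2d"))
  if (!all(dim(mask) == dim(img$pixels))) {
    stopf("`mask` must match the image dimensions")
  }
  px <- img$pixels
  if (max(px) > 0) px <- px / max(px)
  nr <- nrow(px); nc <- ncol(px)
  # central differences with edge replication
  padr <- px[c(1L, seq_len(nr), nr), ]
  padc <- px[, c(1L, seq_len(nc), nc)]
  g_row <- (padr[3:(nr + 2L), ] - padr[seq_len(nr), ]) / 2
  g_col <- (padc[, 3:(nc + 2L)] - padc[, seq_len(nc)]) / 2
  gx <- g_col          # x = column direction
  gy <- -g_row         # y points up while rows run down
  txx <- gy * gy
  tyy <- gx * gx
  txy <- -gx * gy
  cells <- sort(unique(mask[mask > 0L]))
  if (length(cells) == 0L) stopf("`mask` has no labeled ROIs")
  out <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    sel <- mask == cells[j]
    n <- sum(sel)
    if (n < 16L) stopf("ROI %d has %d px; need >= 16", cells[j], n)
    mxx <- mean(txx[sel]); myy <- mean(tyy[sel]); mxy <- mean(txy[sel])
    tr <- mxx + myy
    if (tr <= .Machine$double.eps) {
      out[[j]] <- data.frame(cell = cells[j], theta_M_deg = NA_real_,
                             anisotropy = 0, n_pixels = n,
                             degenerate = TRUE)
      next
    }
    mxx <- mxx / tr; myy <- myy / tr; mxy <- mxy / tr
    disc <- sqrt(max(((mxx - myy) / 2)^2 + mxy^2, 0))
    l1 <- (mxx + myy) / 2 + disc
    l2 <- (mxx + myy) / 2 - disc
    aniso <- l1 - l2
    if (aniso < 1e-12) {
      out[[j]] <- data.frame(cell = cells[j], theta_M_deg = NA_real_,
                             anisotropy = 0, n_pixels = n,
                             degenerate = TRUE)
      next
    }
    v <- if (abs(mxy) > .Machine$double.eps) {
      c(l1 - myy, mxy)
    } else if (mxx >= myy) c(1, 0) else c(0, 1)
    out[[j]] <- data.frame(
      cell = cells[j],
      theta_M_deg = normalize_axial(rad2deg(atan2(v[2], v[1]))),
      anisotropy = aniso, n_pixels = n, degenerate = FALSE
    )
  }
  structure(do.call(rbind, out),
            class = c("fibril_measurements", "data.frame"))
}

#' Population summary of per-cell fibril orientations
#'
#' Runs [nematic_tensor_roi] over all cells of a scene and summarizes
#' the resulting orientations with [axial_summary].  By default each
#' cell's orientation is weighted by its anisotropy, so well-ordered
#' arrays count more than near-isotropic ones; `weight_mode = "none"`
#' gives the unweighted summary.  Degenerate cells are dropped.
#'
#' @param img an [image2d].
#' @param mask integer label matrix of cell ROIs.
#' @param weight_mode `"anisotropy"` (default) or `"none"`.
#' @return A list: `measurements` (the per-cell data frame), `sample`
#'   (the [axial_sample]), `summary` (the [circular_summary]).
#' @export
measure_cells <- function(img, mask,
                          weight_mode = c("anisotropy", "none")) {
  weight_mode <- match.arg(weight_mode)
  meas <- nematic_tensor_roi(img, mask)
  ok <- !meas$degenerate
  if (!any(ok)) stopf("all cells are degenerate (no orientation signal)")
  smp <- axial_sample(
    meas$theta_M_deg[ok],
    if (weight_mode == "anisotropy") meas$anisotropy[ok] else NULL
  )
  list(measurements = meas, sample = smp, summary = axial_summary(smp))
}

#' Acute angle between each cell's fibril orientation and the radial
#' direction from an ablation site
#'
#' For every cell in an ablation scene, the radial direction is the
#' axial angle of the segment from the ablation center to the cell
#' centroid; the score is the acute axial difference between the cell's
#' `theta_M` and that direction, in \[0, 90\] degrees.  90 means the
#' array runs circumferentially around the wound (parallel to the
#' predicted maximal tension), 0 means radial.  Cells with degenerate
#' orientation are skipped with a message.
#'
#' @param scene an `ablation_scene` (see [generate_ablation_scene]), or
#'   any list with `center = c(x, y)` and a `cells` data frame holding
#'   `x_um`, `y_um`, `theta_M_deg`.
#' @return Numeric vector of angles in \[0, 90\], one per retained cell.
#' @export
acute_angle_to_ablation <- function(scene) {
  cells <- scene$cells
  dx <- cells$x_um - scene$center[1]
  dy <- cells$y_um - scene$center[2]
  if (any(dx == 0 & dy == 0)) {
    stopf("a cell centroid coincides with the ablation center")
  }
  ok <- !is.na(cells$theta_M_deg)
  if (any(!ok)) {
    message(sprintf("skipping %d cell(s) with undefined orientation",
                    sum(!ok)))
  }
  radial <- normalize_axial(rad2deg(atan2(dy[ok], dx[ok])))
  axial_difference(cells$theta_M_deg[ok], radial)
}

#' Fisher-Pearson skewness
#'
#' Moment skewness \eqn{g_1 = m_3 / m_2^{3/2}} with biased (population)
#' moments.  For the ablation score, negative skewness means mass piled
#' toward 90 degrees (circumferential).
#'
#' @param x numeric vector.
#' @return The skewness coefficient.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

#' D'Agostino test of skewness against normality
#'
#' Tests whether the sample skewness differs from that of a normal
#' distribution, using D'Agostino's (1970) normalizing transformation of
#' \eqn{g_1} (two-sided).  Needs `n >= 8`.
#'
#' @param x numeric vector.
#' @return A list: `skewness`, `z`, `p_value`, `n`.
#' @export
skewness_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stopf("skewness test needs n >= 8 (got %d)", n)
  g1 <- skewness(x)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(skewness = g1, z = z, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Summarize the fibril reorientation response to an ablation
#'
#' Given the acute-angle scores of the cells around an ablation at two
#' timepoints (typically immediately after wounding and several hours
#' later), reports per-timepoint mean, SD, Fisher-Pearson skewness and
#' its significance against normality ([skewness_test]), the
#' between-timepoint comparison via [compare_linear_samples], and
#' 10-degree-bin histograms.  A reorienting population shifts its mean
#' toward 90 and develops negative skewness.
#'
#' @param t0,t8 numeric vectors of acute angles in \[0, 90\] (n >= 5
#'   each; the skewness test itself needs n >= 8).
#' @param bin_width histogram bin width in degrees.
#' @return An object of class `ablation_summary`: `t0` and `t8` lists
#'   (`mean`, `sd`, `skewness`, `skew_p`, `n`, `hist`), and `comparison`
#'   (a `linear_comparison`).
#' @export
ablation_response_summary <- function(t0, t8, bin_width = 10) {
  if (length(t0) < 5L || length(t8) < 5L) {
    stopf("each timepoint needs n >= 5 angles")
  }
  one <- function(x) {
    st <- skewness_test(x)
    breaks <- seq(0, 90, by = bin_width)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(mean = mean(x), sd = stats::sd(x), skewness = st$skewness,
         skew_p = st$p_value, n = length(x),
         hist = data.frame(bin_start = utils::head(breaks, -1),
                           count = h$counts))
  }
  structure(
    list(t0 = one(t0), t8 = one(t8),
         comparison = compare_linear_samples(t0, t8)),
    class = "ablation_summary"
  )
}

#' @export
print.ablation_summary <- function(x, ...) {
  f <- function(lbl, s) {
    cat(sprintf(
      "  %s: mean %.1f +- %.1f deg, skewness %.2f (p = %.3g), n = %d\n",
      lbl, s$mean, s$sd, s$skewness, s$skew_p, s$n))
  }
  cat("Ablation reorientation response (acute angle to radial, 0-90 deg)\n")
  f("t0", x$t0); f("t8", x$t8)
  cat(sprintf("  t0 vs t8: %s test, p = %.3g\n",
              x$comparison$test_used, x$comparison$p_value))
  invisible(x)
}
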