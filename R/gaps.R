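#' Segment cell-separation regions by intensity threshold
#'
#' Detects separations between cells in a 2D projection by simple
#' intensity thresholding: clear gaps between cells are darker than the
#' stained walls (`polarity = "dark_gap"`, pixels strictly below
#' `threshold` are selected), while incipient separations show up as
#' bright stain-filled stripes (`polarity = "bright_stripe"`, pixels
#' strictly above `threshold`).  Selected pixels are grouped into
#' 8-connected components and components smaller than `min_area` are
#' discarded.
#'
#' The threshold is deliberately a required input -- it varies between
#' images and should be chosen by inspecting each image (see
#' [suggest_threshold] for a documented automatic starting point).
#'
#' @param img an [image2d].
#' @param threshold intensity cut; must lie inside the image intensity
#'   range.
#' @param polarity `"dark_gap"` or `"bright_stripe"`.
#' @param min_area minimum region area in square micrometres (default
#'   5); smaller components are treated as speckle and removed.
#' @return A `label_map`: an integer matrix (0 = background, regions
#'   labeled 1..K) with attributes `scale` (um/px) and `connectivity`
#'   (8).
#' @examples
#' px <- matrix(0.5, 32, 32); px[5:9, 5:9] <- 0.01
#' lab <- segment_separations(image2d(px, 0.5), threshold = 0.1,
#'                            polarity = "dark_gap")
#' max(lab)  # 1 region
#' @export
segment_separations <- function(img, threshold,
                                polarity = c("dark_gap", "bright_stripe"),
                                min_area = 5) {
  stopifnot(inherits(img, "image2d"))
  polarity <- match.arg(polarity)
  rng <- range(img$pixels)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < rng[1] || threshold > rng[2]) {
    stopf("threshold %.4g outside image intensity range [%.4g, %.4g]",
          threshold, rng[1], rng[2])
  }
  mask <- if (polarity == "dark_gap") {
    img$pixels < threshold
  } else {
    img$pixels > threshold
  }
  labels <- label_components_8(mask)
  if (max(labels) > 0L) {
    px_area <- img$scale^2
    tab <- tabulate(labels[labels > 0L])
    keep <- which(tab * px_area >= min_area)
    relab <- integer(length(tab))
    relab[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  structure(labels, scale = img$scale, connectivity = 8L,
            class = c("label_map", class(labels)))
}

# 8-connected component labeling: EBImage::bwlabel (4-connected) followed
# by union of diagonally touching labels.
label_components_8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow = nrow(lab))
  K <- max(lab)
  if (K <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs (down-right and up-right)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) > 0L) {
    parent <- seq_len(K)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(K), find, integer(1))
    relab <- match(root, sort(unique(root)))
    pos <- lab > 0L
    lab[pos] <- relab[lab[pos]]
  }
  lab
}

#' Automatic threshold starting point (Otsu)
#'
#' Computes Otsu's threshold on the image histogram as a documented,
#' reproducible starting point for [segment_separations].  It is a
#' fallback, never a silent default: separation contrast varies between
#' images and the threshold should be confirmed visually.
#'
#' @param img an [image2d] with intensities in \[0, 1\].
#' @return A single threshold value.
#' @export
suggest_threshold <- function(img) {
  stopifnot(inherits(img, "image2d"))
  px <- pmin(pmax(img$pixels, 0), 1)
  EBImage::otsu(EBImage::Image(px), range = c(0, 1))
}

#' Measure area, orientation and anisotropy of labeled regions
#'
#' For each labeled region, computes its physical area (pixel count
#' times scale squared), centroid, and the principal-component
#' orientation of its pixel cloud: the covariance matrix of the pixel
#' coordinates is eigen-decomposed; `theta_G` is the axial angle of the
#' leading eigenvector (degrees counter-clockwise from the image
#' horizontal, in \eqn{[0,180)}) and the anisotropy is the normalized
#' eigenvalue difference \eqn{(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)
#' \in [0,1]}.  Single-pixel regions and regions with equal principal
#' moments have no defined orientation: they are flagged `degenerate`
#' with anisotropy 0 and `theta_G = NA`.
#'
#' @param labels a `label_map` from [segment_separations], or an integer
#'   matrix (0 = background).
#' @param scale micrometres per pixel; defaults to the `scale` attribute
#'   of `labels`.
#' @return A data frame of class `gap_regions`, one row per region:
#'   `label`, `area_um2`, `centroid_x_um`, `centroid_y_um` (x = column
#'   direction, y = row direction measured upward from the bottom edge),
#'   `theta_G_deg`, `anisotropy`, `degenerate`, `n_pixels`.  Empty label
#'   map gives an empty data frame.
#' @export
measure_regions <- function(labels, scale = attr(labels, "scale")) {
  if (is.null(scale)) stopf("no `scale` given and none attached to labels")
  if (!is.numeric(scale) || scale <= 0) stopf("`scale` must be positive")
  lab <- unclass(labels)
  K <- max(lab)
  empty <- data.frame(
    label = integer(0), area_um2 = numeric(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    theta_G_deg = numeric(0), anisotropy = numeric(0),
    degenerate = logical(0), n_pixels = integer(0)
  )
  if (K < 1L) return(structure(empty, class = c("gap_regions", "data.frame")))
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  ll <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  out <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- ll == k
    r <- rows[sel]; cc <- cols[sel]
    n <- length(r)
    mom <- region_moments(r, cc)
    out[[k]] <- data.frame(
      label = k,
      area_um2 = n * scale^2,
      centroid_x_um = mean(cc - 0.5) * scale,
      centroid_y_um = (nr - mean(r - 0.5)) * scale,
      theta_G_deg = mom$theta,
      anisotropy = mom$anisotropy,
      degenerate = mom$degenerate,
      n_pixels = n
    )
  }
  structure(do.call(rbind, out), class = c("gap_regions", "data.frame"))
}

# Second-moment orientation of a pixel cloud given row/col indices.
# Uses math coordinates x = col, y = -row so angles are counter-clockwise
# from the horizontal when rows run downward.
region_moments <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) {
    return(list(theta = NA_real_, anisotropy = 0, degenerate = TRUE))
  }
  x <- cols - mean(cols)
  y <- -(rows - mean(rows))
  sxx <- sum(x * x) / n
  syy <- sum(y * y) / n
  sxy <- sum(x * y) / n
  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  disc <- sqrt(max((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (tr <= 0 || (l1 - l2) / tr < 1e-9) {
    return(list(theta = NA_real_, anisotropy = 0, degenerate = TRUE))
  }
  # leading eigenvector of [[sxx, sxy], [sxy, syy]]
  v <- if (abs(sxy) > .Machine$double.eps * tr) {
    c(l1 - syy, sxy)
  } else if (sxx >= syy) c(1, 0) else c(0, 1)
  theta <- normalize_axial(rad2deg(atan2(v[2], v[1])))
  list(theta = theta, anisotropy = (l1 - l2) / (l1 + l2),
       degenerate = FALSE)
}

#' Summarize a field's cell-separation regions
#'
#' Aggregates per-region measurements into per-image totals: total
#' separated area, the percent fraction of the imaged field that has
#' separated, the number of regions, and an [axial_sample] of region
#' orientations ready for [axial_summary] and [rao_spacing_test].
#' Degenerate regions (undefined orientation) count toward the area
#' totals but are excluded from the orientation sample.
#'
#' @param regions a `gap_regions` data frame from [measure_regions].
#' @param field_area imaged field area in square micrometres (> 0).
#' @param weight_mode weighting of the orientation sample:
#'   `"none"` (default for separations), `"anisotropy"`, or `"area"`.
#' @return An object of class `gap_summary`: `total_gap_area`,
#'   `field_area`, `gap_fraction` (percent), `n_regions`, `orientations`
#'   (an [axial_sample]).
#' @examples
#' regs <- data.frame(label = 1, area_um2 = 17906, centroid_x_um = 0,
#'                    centroid_y_um = 0, theta_G_deg = 90, anisotropy = 0.8,
#'                    degenerate = FALSE, n_pixels = 100)
#' summarize_gaps(regs, field_area = 138654)$gap_fraction  # ~12.9%
#' @export
summarize_gaps <- function(regions, field_area,
                           weight_mode = c("none", "anisotropy", "area")) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(field_area) || field_area <= 0) {
    stopf("`field_area` must be positive")
  }
  total <- sum(regions$area_um2)
  if (total > field_area) {
    stopf("total gap area %.4g exceeds field area %.4g", total, field_area)
  }
  ok <- !regions$degenerate
  ang <- regions$theta_G_deg[ok]
  w <- switch(weight_mode,
    none = NULL,
    anisotropy = regions$anisotropy[ok],
    area = regions$area_um2[ok]
  )
  orientations <- if (length(ang) > 0L) {
    axial_sample(ang, w)
  } else {
    axial_sample(numeric(0))
  }
  structure(
    list(total_gap_area = total, field_area = field_area,
         gap_fraction = 100 * total / field_area,
         n_regions = nrow(regions), orientations = orientations,
         weight_mode = weight_mode),
    class = "gap_summary"
  )
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf(
    "Cell-separation summary: %d region(s), %.0f um^2 of %.0f um^2 (%.2f%%)\n",
    x$n_regions, x$total_gap_area, x$field_area, x$gap_fraction
  ))
  cat(sprintf("  orientation sample: n = %d (%s-weighted)\n",
              length(x$orientations), x$weight_mode))
  invisible(x)
}

#' Overlay segmented regions and their principal axes on an image
#'
#' Draws the grayscale image with each detected region tinted and a line
#' segment through its centroid along `theta_G`, scaled by anisotropy --
#' the standard visual check that segmentation and orientation measures
#' are sensible.
#'
#' @param img an [image2d].
#' @param regions `gap_regions` from [measure_regions].
#' @param labels optional `label_map` used to tint region pixels.
#' @param axis_length_um half-length of the orientation segments, in
#'   micrometres (default: sqrt of the mean region area).
#' @return `regions`, invisibly.
#' @export
plot_gap_overlay <- function(img, regions, labels = NULL,
                             axis_length_um = NULL) {
  stopifnot(inherits(img, "image2d"))
  nr <- nrow(img$pixels); ncl <- ncol(img$pixels)
  plot(img)
  # plot.image2d draws on a [0,1]x[0,1] canvas; convert um to that frame
  ux <- function(x_um) x_um / (ncl * img$scale)
  uy <- function(y_um) y_um / (nr * img$scale)
  if (nrow(regions) == 0L) return(invisible(regions))
  if (is.null(axis_length_um)) {
    axis_length_um <- sqrt(mean(regions$area_um2))
  }
  ok <- !regions$degenerate
  th <- deg2rad(regions$theta_G_deg[ok])
  len <- axis_length_um * regions$anisotropy[ok]
  x0 <- regions$centroid_x_um[ok] - len * cos(th)
  x1 <- regions$centroid_x_um[ok] + len * cos(th)
  y0 <- regions$centroid_y_um[ok] - len * sin(th)
  y1 <- regions$centroid_y_um[ok] + len * sin(th)
  graphics::points(ux(regions$centroid_x_um), uy(regions$centroid_y_um),
                   col = "red", pch = 3, cex = 0.6)
  graphics::segments(ux(x0), uy(y0), ux(x1), uy(y1), col = "red", lwd = 2)
  invisible(regions)
}
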