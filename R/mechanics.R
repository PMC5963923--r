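#' AFM force-indentation curve
#'
#' A force-displacement record from an indentation experiment:
#' indentation depth `Z` (micrometres, strictly increasing) against
#' force `F` (micronewtons), with optional probe metadata.
#'
#' @param Z indentation depths, micrometres; strictly increasing, length
#'   >= 10.
#' @param F forces, micronewtons; same length as `Z`.
#' @param probe_radius_um optional probe tip radius.
#' @param label optional curve label.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(Z, F, probe_radius_um = NA_real_, label = "") {
  Z <- as.numeric(Z); F <- as.numeric(F)
  if (length(Z) != length(F)) stopf("`Z` and `F` must have equal length")
  if (length(Z) < 10L) stopf("a force curve needs >= 10 points")
  if (any(diff(Z) <= 0)) stopf("`Z` must be strictly increasing")
  structure(
    list(Z_um = Z, F_uN = F, probe_radius_um = probe_radius_um,
         label = label),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve%s> %d points, Z up to %.3g um, F up to %.3g uN\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    length(x$Z_um), max(x$Z_um), max(x$F_uN)))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$Z_um, x$F_uN, type = "l",
                 xlab = "Z (um)", ylab = "F (uN)", ...)
  if (!is.null(fit)) {
    sel <- fit$window_points
    graphics::lines(x$Z_um[sel], fit$intercept + fit$k * x$Z_um[sel],
                    col = "red", lty = 2, lwd = 2)
  }
  invisible(x)
}

#' Apparent stiffness from the deep-indentation slope
#'
#' Extracts the apparent stiffness `k` of a force-indentation curve as
#' the ordinary least-squares slope of F against Z restricted to the
#' deep-indentation window -- by default the points whose force lies
#' between 75% and 99% of the maximal force, where the response is
#' dominated by turgor and close to linear.  Since 1 uN/um = 1 N/m, the
#' fitted slope is reported directly in N/m.
#'
#' @param curve a [force_curve].
#' @param window lower/upper bounds of the fit window as fractions of
#'   the maximal force, `0 < lo < hi <= 1` (default `c(0.75, 0.99)`).
#' @return An object of class `stiffness_fit`: `k` (N/m), `intercept`
#'   (uN), `window`, `n_points_in_window`, `r_squared`,
#'   `window_points` (indices used).
#' @examples
#' cv <- generate_force_curve("linear", true_slope = 3)
#' apparent_stiffness(cv)$k  # 3
#' @export
apparent_stiffness <- function(curve, window = c(0.75, 0.99)) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(window) != 2L || window[1] <= 0 || window[1] >= window[2] ||
      window[2] > 1) {
    stopf("`window` must satisfy 0 < lo < hi <= 1")
  }
  Fmax <- max(curve$F_uN)
  sel <- which(curve$F_uN >= window[1] * Fmax &
               curve$F_uN <= window[2] * Fmax)
  if (length(sel) < 3L) {
    stopf("only %d point(s) fall in the [%g, %g] x F_max window; need >= 3",
          length(sel), window[1], window[2])
  }
  fit <- stats::lm(curve$F_uN[sel] ~ curve$Z_um[sel])
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k)) stopf("degenerate fit window (constant Z)")
  sst <- sum((curve$F_uN[sel] - mean(curve$F_uN[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(k = k, intercept = unname(stats::coef(fit)[1]), window = window,
         n_points_in_window = length(sel),
         r_squared = r2, window_points = sel),
    class = "stiffness_fit"
  )
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf(
    "Apparent stiffness k = %.4g N/m (window %g-%g of F_max, %d points, r^2 = %.4f)\n",
    x$k, x$window[1], x$window[2], x$n_points_in_window, x$r_squared))
  invisible(x)
}

#' Shell radius from surface mean curvature
#'
#' In the spherical thin-shell model the vessel radius is the inverse of
#' the cell-surface mean curvature.  Flat or saddle-like surfaces
#' (non-positive curvature) are outside the model and raise an error.
#'
#' @param mean_curvature surface mean curvature in 1/um (> 0).
#' @return Radius in micrometres.
#' @examples
#' radius_from_curvature(0.1)  # 10 um
#' @export
radius_from_curvature <- function(mean_curvature) {
  if (any(!is.finite(mean_curvature)) || any(mean_curvature <= 0)) {
    stopf("mean curvature must be positive (spherical shell model)")
  }
  1 / mean_curvature
}

#' Thin-shell wall tension of a pressurized spherical cell
#'
#' Treats the cell as a spherical thin-walled pressure vessel: the wall
#' stress is \eqn{\sigma = P r / (2 t)} with turgor pressure `P` (MPa),
#' radius `r` (um, typically from [radius_from_curvature]) and wall
#' thickness `t` (um; default 0.2 um = 200 nm, a standard value for the
#' outer periclinal wall).  Units are consistent: MPa x um / um = MPa.
#'
#' @param P turgor pressure, MPa (>= 0).
#' @param r shell radius, micrometres (> 0).
#' @param t wall thickness, micrometres (> 0; default 0.2).
#' @return Wall tension sigma in MPa.
#' @examples
#' wall_tension(P = 1, r = 10, t = 0.2)  # 25 MPa
#' @export
wall_tension <- function(P, r, t = 0.2) {
  if (any(P < 0)) stopf("turgor pressure must be non-negative")
  if (any(r <= 0)) stopf("radius must be positive")
  if (any(t <= 0)) stopf("wall thickness must be positive")
  P * r / (2 * t)
}

#' Aggregate per-curve stiffness to cells
#'
#' AFM protocols take several force curves per cell (typically at least
#' nine); this helper fits [apparent_stiffness] to each curve and
#' reports the mean and SD of `k` per cell id.
#'
#' @param curves list of [force_curve] objects.
#' @param cell_ids vector of cell identifiers, one per curve.
#' @param window passed to [apparent_stiffness].
#' @return Data frame: `cell`, `k_mean`, `k_sd`, `n_curves`.
#' @export
stiffness_by_cell <- function(curves, cell_ids, window = c(0.75, 0.99)) {
  if (length(curves) != length(cell_ids)) {
    stopf("`cell_ids` must have one entry per curve")
  }
  k <- vapply(curves, function(cv) apparent_stiffness(cv, window)$k,
              numeric(1))
  sp <- split(k, cell_ids)
  data.frame(
    cell = names(sp),
    k_mean = vapply(sp, mean, numeric(1)),
    k_sd = vapply(sp, stats::sd, numeric(1)),
    n_curves = vapply(sp, length, integer(1)),
    row.names = NULL
  )
}
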