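#' Axial orientation sample
#'
#' A population of axial angles (orientations, where \eqn{\theta} and
#' \eqn{\theta + 180^\circ} are the same object) with optional
#' non-negative weights.  Angles are stored in degrees on \eqn{[0, 180)};
#' out-of-range input is reduced modulo 180.
#'
#' @param angles numeric vector of orientations in degrees.
#' @param weights optional non-negative weights of the same length (e.g.
#'   per-cell anisotropy, or region area); must not be all zero.
#' @return An object of class `axial_sample`.
#' @examples
#' axial_sample(c(10, 20, 30))
#' @export
axial_sample <- function(angles, weights = NULL) {
  angles <- as.numeric(angles)
  if (anyNA(angles)) stopf("`angles` contains NA")
  angles <- normalize_axial(angles)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(angles)) {
      stopf("`weights` must match `angles` in length")
    }
    if (anyNA(weights) || any(weights < 0)) {
      stopf("`weights` must be non-negative and free of NA")
    }
    if (length(weights) > 0L && sum(weights) == 0) {
      stopf("`weights` must not be all zero")
    }
  }
  structure(list(angles = angles, weights = weights),
            class = "axial_sample")
}

#' @export
print.axial_sample <- function(x, ...) {
  cat(sprintf("<axial_sample> n = %d%s\n", length(x$angles),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' @export
length.axial_sample <- function(x) length(x$angles)

as_axial_sample <- function(x, weights = NULL) {
  if (inherits(x, "axial_sample")) x else axial_sample(x, weights)
}

#' Circular summary of an axial sample
#'
#' Computes the (optionally weighted) circular mean, resultant vector
#' length \eqn{R} and circular standard deviation of a set of
#' orientations.  Axial data are handled by the standard doubling device:
#' angles are doubled onto the full circle, the weighted mean resultant
#' vector is formed there, and the mean direction is halved back.  \eqn{R}
#' lies in \eqn{[0, 1]}: 1 means all orientations coincide, values near 0
#' mean no preferred orientation.  The circular SD is
#' \eqn{\sqrt{-2\ln R}/2} (computed on the doubled circle, then halved),
#' reported in degrees.
#'
#' When the resultant vanishes (\eqn{R = 0}, e.g. two orthogonal
#' orientations with equal weight) the mean is undefined: it is reported
#' as `NA` with `mean_defined = FALSE` and the SD is `Inf`; this is not
#' an error.
#'
#' @param sample an [axial_sample], or a numeric vector of degrees.
#' @param weights optional weights when `sample` is a bare vector.
#' @return An object of class `circular_summary` with elements `mean`
#'   (degrees in \eqn{[0,180)}), `sd` (degrees), `R`, `n`, `weighted`,
#'   `mean_defined`.
#' @examples
#' s <- axial_summary(c(10, 20, 30))
#' s$mean  # 20
#' s$R     # ~0.96
#' @export
axial_summary <- function(sample, weights = NULL) {
  sample <- as_axial_sample(sample, weights)
  n <- length(sample$angles)
  if (n < 1L) stopf("need at least one angle")
  w <- sample$weights
  weighted <- !is.null(w)
  if (!weighted) w <- rep(1, n)
  phi <- deg2rad(2 * sample$angles)          # doubled angles
  C <- sum(w * cos(phi)) / sum(w)
  S <- sum(w * sin(phi)) / sum(w)
  R <- sqrt(C^2 + S^2)
  if (R < .Machine$double.eps^0.5) {
    mean_deg <- NA_real_
    sd_deg <- Inf
    defined <- FALSE
    R <- max(R, 0)
  } else {
    mean_deg <- normalize_axial(rad2deg(atan2(S, C)) / 2)
    sd_deg <- rad2deg(sqrt(-2 * log(R))) / 2
    defined <- TRUE
  }
  structure(
    list(mean = mean_deg, sd = sd_deg, R = R, n = n,
         weighted = weighted, mean_defined = defined),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "Axial circular summary (n = %d%s)\n", x$n,
    if (x$weighted) ", weighted" else ""
  ))
  if (x$mean_defined) {
    cat(sprintf("  mean %.1f deg +- %.1f deg,  R = %.3f\n",
                x$mean, x$sd, x$R))
  } else {
    cat(sprintf("  mean undefined (R = %.3g)\n", x$R))
  }
  invisible(x)
}

# Rao spacing statistic on doubled angles; angles in degrees on [0, 180).
# Returns U in degrees of the doubled circle.
rao_spacing_statistic <- function(angles) {
  n <- length(angles)
  a <- sort((2 * angles) %% 360)
  spacings <- c(diff(a), 360 - a[n] + a[1L])
  0.5 * sum(abs(spacings - 360 / n))
}

# Null sample of the Rao statistic for n uniform angles.  Uses the
# Dirichlet representation of circular spacings (normalized exponentials),
# which avoids per-replicate sorting.
rao_null_sample <- function(n, reps) {
  E <- matrix(stats::rexp(n * reps), nrow = reps)
  T <- 360 * E / rowSums(E)
  0.5 * rowSums(abs(T - 360 / n))
}

#' Rao's spacing test of uniformity for axial data
#'
#' Tests whether orientations are spread homogeneously over the axial
#' range against an alternative of clustering around one or more
#' preferred orientations.  Angles are doubled onto the full circle and
#' sorted; with circular spacings \eqn{T_i} (including the wrap-around
#' gap) the statistic is \eqn{U = \frac{1}{2}\sum_i |T_i - 360/n|}
#' degrees.  Large \eqn{U} means uneven spacing, i.e. non-uniformity.
#'
#' The p-value is obtained from a seeded Monte-Carlo null of `mc_reps`
#' samples of \eqn{n} uniform angles (ties in the data are allowed).
#' Weights attached to the sample are ignored by this test.
#'
#' @param sample an [axial_sample] or numeric vector of degrees; `n >= 4`.
#' @param mc_reps number of Monte-Carlo null replicates.
#' @param seed integer seed for the null simulation (`NULL` = current RNG).
#' @param null_sample optional precomputed vector of null statistics for
#'   this `n` (see [rao_null_distribution]); overrides `mc_reps`/`seed`.
#' @return An object of class `rao_test` with `statistic` (U, degrees on
#'   the doubled circle), `p_value`, `n`, `method`, `mc_reps`, `seed`.
#' @examples
#' rao_spacing_test(c(88, 90, 92, 89, 91, 90.5), mc_reps = 2000, seed = 1)
#' @export
rao_spacing_test <- function(sample, mc_reps = 10000L, seed = NULL,
                             null_sample = NULL) {
  sample <- as_axial_sample(sample)
  n <- length(sample$angles)
  if (n < 4L) stopf("Rao's spacing test needs n >= 4 (got %d)", n)
  U <- rao_spacing_statistic(sample$angles)
  if (is.null(null_sample)) {
    null_sample <- with_seed(seed, rao_null_sample(n, mc_reps))
  }
  reps <- length(null_sample)
  # add-one MC p-value: never exactly zero
  p <- (sum(null_sample >= U) + 1) / (reps + 1)
  structure(
    list(statistic = U, p_value = p, n = n, method = "monte_carlo",
         mc_reps = reps, seed = seed),
    class = "rao_test"
  )
}

#' Precompute a Rao null distribution for repeated testing
#'
#' When many samples of the same size are tested, the uniform null of the
#' spacing statistic can be drawn once and reused via the `null_sample`
#' argument of [rao_spacing_test].
#'
#' @param n sample size.
#' @param mc_reps number of null replicates.
#' @param seed integer seed.
#' @return Numeric vector of null statistics (degrees).
#' @export
rao_null_distribution <- function(n, mc_reps = 10000L, seed = NULL) {
  with_seed(seed, rao_null_sample(n, mc_reps))
}

#' @export
print.rao_test <- function(x, ...) {
  cat(sprintf(
    "Rao's spacing test (axial): U = %.2f deg, n = %d, p = %.4g (%s, %d reps)\n",
    x$statistic, x$n, x$p_value, x$method, x$mc_reps
  ))
  invisible(x)
}

#' Polar histogram of an axial sample
#'
#' Bins (optionally weighted) orientations into axial bins of
#' `bin_width` degrees and optionally draws the standard polar rose, with
#' the half-circle mirrored to the full circle for display (each axial bin
#' appears twice, at \eqn{\theta} and \eqn{\theta + 180^\circ}).
#'
#' @param sample an [axial_sample] or numeric vector of degrees (may be
#'   empty: all bins are zero).
#' @param bin_width bin width in degrees; must divide 180.
#' @param plot draw the rose (base graphics) or just return the counts.
#' @param main plot title.
#' @return Invisibly, a data frame with `bin_start`, `bin_mid`, `count`
#'   (weighted counts per axial bin).
#' @export
polar_histogram <- function(sample, bin_width = 10, plot = TRUE,
                            main = "Orientation distribution") {
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      bin_width <= 0 || (180 %% bin_width) != 0) {
    stopf("`bin_width` must be a positive divisor of 180")
  }
  sample <- as_axial_sample(sample)
  nb <- as.integer(180 / bin_width)
  counts <- numeric(nb)
  if (length(sample$angles) > 0L) {
    w <- sample$weights
    if (is.null(w)) w <- rep(1, length(sample$angles))
    idx <- pmin(floor(sample$angles / bin_width) + 1L, nb)
    for (i in seq_along(idx)) counts[idx[i]] <- counts[idx[i]] + w[i]
  }
  starts <- (seq_len(nb) - 1L) * bin_width
  out <- data.frame(bin_start = starts, bin_mid = starts + bin_width / 2,
                    count = counts)
  if (plot) {
    rmax <- max(counts, 1e-12)
    graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = main)
    for (i in seq_len(nb)) {
      for (off in c(0, 180)) {   # mirror axial bins
        a0 <- deg2rad(starts[i] + off)
        a1 <- deg2rad(starts[i] + bin_width + off)
        r <- counts[i] / rmax
        aa <- seq(a0, a1, length.out = 8)
        graphics::polygon(c(0, r * cos(aa)), c(0, r * sin(aa)),
                          col = "grey40", border = "white")
      }
    }
    tt <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(cos(tt), sin(tt), col = "grey70")
  }
  invisible(out)
}

#' Compare two linear samples with normality-gated test selection
#'
#' Implements the standard decision tree for comparing two samples of
#' linear (non-circular) measurements: Shapiro-Wilk normality on each
#' sample; if either is non-normal at `alpha`, a Wilcoxon rank-sum test;
#' if both normal, Bartlett's test of equal variances, then Student's
#' t-test (equal variances) or Welch's t-test (unequal).  Constant
#' samples (zero variance, for which Shapiro is undefined) fall through
#' to the Wilcoxon branch with a warning.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alpha significance level used for the Shapiro and Bartlett
#'   gates (default 0.05).
#' @return An object of class `linear_comparison`: `test_used`
#'   (`"student"`, `"welch"` or `"wilcoxon"`), `p_value`, and
#'   `branch_trace` recording the gate p-values.
#' @examples
#' set.seed(1)
#' compare_linear_samples(rnorm(20), rnorm(20, 1))
#' @export
compare_linear_samples <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stopf("each sample needs n >= 3")
  }
  trace <- list(shapiro_a = NA_real_, shapiro_b = NA_real_,
                bartlett = NA_real_)
  constant <- (stats::sd(a) == 0 || stats::sd(b) == 0)
  if (constant) {
    warnf("constant sample: normality undefined, using Wilcoxon rank-sum")
    normal <- FALSE
  } else {
    trace$shapiro_a <- stats::shapiro.test(a)$p.value
    trace$shapiro_b <- stats::shapiro.test(b)$p.value
    normal <- trace$shapiro_a >= alpha && trace$shapiro_b >= alpha
  }
  if (!normal) {
    test_used <- "wilcoxon"
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  } else {
    trace$bartlett <- stats::bartlett.test(list(a, b))$p.value
    if (trace$bartlett >= alpha) {
      test_used <- "student"
      p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    } else {
      test_used <- "welch"
      p <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  }
  structure(
    list(test_used = test_used, p_value = p, alpha = alpha,
         branch_trace = trace),
    class = "linear_comparison"
  )
}

#' @export
print.linear_comparison <- function(x, ...) {
  cat(sprintf("Two-sample comparison: %s test, p = %.4g\n",
              x$test_used, x$p_value))
  tr <- x$branch_trace
  cat(sprintf("  gates: Shapiro a/b p = %.3g / %.3g; Bartlett p = %.3g\n",
              tr$shapiro_a, tr$shapiro_b, tr$bartlett))
  invisible(x)
}
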