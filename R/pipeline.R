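#' Configuration for the gap-analysis pipeline
#'
#' A fully serializable description of one batch run of the
#' separation-detection pipeline: image paths (or in-memory [image2d]
#' objects), the segmentation threshold and polarity, the speckle
#' filter, the physical scale, the organ-axis convention, orientation
#' weighting, histogram binning and the seed of the uniformity test.
#'
#' Angles are measured from the image horizontal; `organ_axis` is the
#' axial angle of the organ's long axis in the image (default 90,
#' i.e. vertical), and reported orientations are rotated by
#' `-(organ_axis - 90)` so that 90 always means "along the organ axis"
#' and 0 "transverse to it", whichever way the organ lies in the frame.
#'
#' @param images character vector of image paths, or a list of
#'   [image2d] objects (named for reporting).
#' @param threshold segmentation threshold (required; see
#'   [suggest_threshold] for a starting point).
#' @param polarity `"dark_gap"` or `"bright_stripe"`.
#' @param min_area speckle filter in um^2.
#' @param scale um/px used when reading image files (`NULL`: rely on
#'   sidecars).
#' @param organ_axis axial angle of the organ axis in the image,
#'   degrees.
#' @param weight_mode orientation weighting for [summarize_gaps].
#' @param bin_width polar histogram bin width, degrees.
#' @param seed seed for the Rao uniformity test.
#' @param mc_reps Monte-Carlo replicates for the uniformity test.
#' @param out_dir optional output directory for CSV/JSON tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(images, threshold,
                            polarity = c("dark_gap", "bright_stripe"),
                            min_area = 5, scale = NULL, organ_axis = 90,
                            weight_mode = c("none", "anisotropy", "area"),
                            bin_width = 10, seed = 1L, mc_reps = 10000L,
                            out_dir = NULL) {
  polarity <- match.arg(polarity)
  weight_mode <- match.arg(weight_mode)
  structure(
    list(images = images, threshold = threshold, polarity = polarity,
         min_area = min_area, scale = scale, organ_axis = organ_axis,
         weight_mode = weight_mode, bin_width = bin_width,
         seed = as.integer(seed), mc_reps = as.integer(mc_reps),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration
#'
#' Configurations round-trip through JSON so that a run is fully
#' described by one declarative file.  Only path-based configs are
#' serializable (in-memory images are a programmatic convenience).
#'
#' @param config a [pipeline_config].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.character(config$images)) {
    stopf("only path-based configs can be serialized")
  }
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the separation-detection pipeline over a batch of images
#'
#' For each image: segment separations ([segment_separations]), measure
#' regions ([measure_regions]), summarize ([summarize_gaps]), and pool
#' all region orientations across images into one axial sample that is
#' summarized ([axial_summary]) and tested for uniformity
#' ([rao_spacing_test]).  Per-image failures are logged and skipped; the
#' run fails only if every image fails.
#'
#' @param config a [pipeline_config].
#' @return An object of class `run_report`: `per_image` (named list
#'   with `summary`, `regions`, `n_regions`), `pooled` (list with
#'   `sample`, `summary`, `rao`), `config`, `failed` (names of skipped
#'   images).
#' @export
run_gap_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  imgs <- config$images
  nm <- if (is.character(imgs)) basename(imgs) else {
    if (is.null(names(imgs))) paste0("image_", seq_along(imgs)) else names(imgs)
  }
  per_image <- list()
  failed <- character(0)
  all_angles <- numeric(0)
  all_weights <- numeric(0)
  for (i in seq_along(imgs)) {
    res <- tryCatch({
      img <- if (is.character(imgs)) {
        read_image(imgs[[i]], scale = config$scale)
      } else {
        imgs[[i]]
      }
      labels <- segment_separations(img, config$threshold,
                                    config$polarity, config$min_area)
      regions <- measure_regions(labels)
      # rotate into the organ-axis convention (90 = along the organ)
      rot <- config$organ_axis - 90
      regions$theta_G_deg <- ifelse(
        is.na(regions$theta_G_deg), NA_real_,
        normalize_axial(regions$theta_G_deg - rot))
      field_area <- prod(dim(img)) * img$scale^2
      summ <- summarize_gaps(regions, field_area, config$weight_mode)
      list(summary = summ, regions = regions, n_regions = nrow(regions))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[%s] FAILED: %s", nm[i], conditionMessage(res)))
      failed <- c(failed, nm[i])
      next
    }
    message(sprintf("[%s] %d region(s), %.2f%% of field separated",
                    nm[i], res$n_regions, res$summary$gap_fraction))
    per_image[[nm[i]]] <- res
    smp <- res$summary$orientations
    if (length(smp) > 0L) {
      all_angles <- c(all_angles, smp$angles)
      w <- smp$weights
      all_weights <- c(all_weights,
                       if (is.null(w)) rep(1, length(smp$angles)) else w)
    }
  }
  if (length(per_image) == 0L) stopf("all images failed")
  pooled_sample <- if (length(all_angles) > 0L) {
    axial_sample(all_angles,
                 if (config$weight_mode == "none") NULL else all_weights)
  } else {
    axial_sample(numeric(0))
  }
  pooled <- list(
    sample = pooled_sample,
    summary = if (length(pooled_sample) > 0L) axial_summary(pooled_sample),
    rao = if (length(pooled_sample) >= 4L) {
      rao_spacing_test(pooled_sample, config$mc_reps, config$seed)
    }
  )
  report <- structure(
    list(per_image = per_image, pooled = pooled, config = config,
         failed = failed),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Gap-pipeline report: %d image(s) analyzed, %d failed\n",
              length(x$per_image), length(x$failed)))
  for (nm in names(x$per_image)) {
    s <- x$per_image[[nm]]$summary
    cat(sprintf("  %s: %d region(s), %.2f%%\n", nm, s$n_regions,
                s$gap_fraction))
  }
  if (!is.null(x$pooled$summary)) {
    cat("Pooled orientations:\n  ")
    print(x$pooled$summary)
  }
  if (!is.null(x$pooled$rao)) {
    cat("  ")
    print(x$pooled$rao)
  }
  invisible(x)
}

# Write the report tables (per-image region CSVs + JSON summary).
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$per_image)) {
    utils::write.csv(report$per_image[[nm]]$regions,
                     file.path(out_dir, paste0(nm, "_regions.csv")),
                     row.names = FALSE)
  }
  pooled <- report$pooled
  summ <- lapply(report$per_image, function(r) {
    s <- r$summary
    list(n_regions = s$n_regions, total_gap_area_um2 = s$total_gap_area,
         field_area_um2 = s$field_area, gap_fraction_pct = s$gap_fraction)
  })
  out <- list(
    per_image = summ,
    pooled = if (!is.null(pooled$summary)) list(
      mean_deg = pooled$summary$mean, sd_deg = pooled$summary$sd,
      R = pooled$summary$R, n = pooled$summary$n,
      rao_U = if (!is.null(pooled$rao)) pooled$rao$statistic,
      rao_p = if (!is.null(pooled$rao)) pooled$rao$p_value
    ),
    failed = report$failed
  )
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}
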