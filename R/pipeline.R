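#' Configuration for the end-to-end synthetic experiment
#'
#' Collects every stage's parameters with defaults reproducing the
#' three-zone partial-ischemia scenario: a 40 s, 25 fps fluorescence video,
#' reference-card normalization, StO2 zone classification at 33/63 percent,
#' landmark registration, per-zone capillary phantoms and a six-subject
#' lactate cohort.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param scene,video,fler,classify,mls,fcda,cohort Named lists overriding
#'   individual stage defaults (partial lists are merged over the defaults).
#' @return Object of class `perf_config`.
#' @export
perf_config <- function(seed = 1, scene = list(), video = list(),
                        fler = list(), classify = list(), mls = list(),
                        fcda = list(), cohort = list()) {
  merge <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    seed = as.integer(seed),
    scene = merge(list(height = 96, width = 96, ref_size = 12), scene),
    video = merge(list(duration = 40, fps = 25, noise_sd = 1,
                       ref_intensity = 50, background_level = 1,
                       attenuation = 1), video),
    fler = merge(list(smooth_window = 5, min_delta = 0.02,
                      baseline_frames = 5), fler),
    classify = merge(list(t_low = 33, t_high = 63, min_size = 25), classify),
    mls = merge(list(alpha = 1, grid_step = 4), mls),
    fcda = merge(list(fov_radius = 120, frames_per_zone = 3,
                      min_elongation = 3, min_area = 50, blur_sigma = 1),
                 fcda),
    cohort = merge(list(n_subjects = 6, lcl_noise_sd = 0.3), cohort)
  ), class = "perf_config")
}

#' Run the full synthetic perfusion experiment
#'
#' Executes every stage on generated data: scene and fluorescence video,
#' reference normalization and slope cartography, StO2 map and
#' threshold-based zone classification, moving-least-squares registration of
#' the StO2 map onto the cartography grid, per-zone capillary phantoms with
#' the FCD-A index, and the lactate cohort with both exponential prediction
#' models, leave-one-subject-out cross-validation, the paired Wilcoxon model
#' comparison, Spearman correlations and the correlation sample size. The
#' run is deterministic in `config$seed`.
#'
#' @param config A [perf_config()].
#' @param out_dir Optional directory; when given, intermediate images
#'   (TIFF), the cohort CSV and the report JSON are written there.
#' @return Object of class `run_report`.
#' @export
run_experiment <- function(config = perf_config(), out_dir = NULL) {
  stopifnot(inherits(config, "perf_config"))
  seed <- config$seed
  zl <- c("vital", "transition", "ischemic")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- default_scene_layout(config$scene$height, config$scene$width,
                                 config$scene$ref_size)
  zones <- default_zones()

  video <- do.call(generate_fluorescence_video,
                   c(list(layout = layout, zones = zones, seed = seed + 11L),
                     config$video))
  norm <- normalize_by_reference(video)
  slope <- do.call(compute_slope_map, c(list(video = norm), config$fler))

  sto2 <- generate_sto2_map(layout, zones, seed = seed + 13L)
  rois <- do.call(classify_zones, c(list(map = sto2), config$classify))

  zone_stats <- do.call(rbind, lapply(zl, function(z) {
    sel_s <- rois[[z]] & sto2$valid_mask
    sel_f <- rois[[z]] & slope$valid_mask
    data.frame(zone = z,
               sto2_mean = mean(sto2$sto2[sel_s]),
               sto2_sd = stats::sd(sto2$sto2[sel_s]),
               slope_mean = mean(slope$slope[sel_f]),
               slope_sd = stats::sd(slope$slope[sel_f]),
               n_pixels = sum(rois[[z]]))
  }))

  # registration: a known mild affine perturbation supplies the landmark
  # pairs (stand-in for manually picked features)
  theta <- 0.05; shift <- c(3, -2)
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  ctr <- c(config$scene$width, config$scene$height) / 2
  src <- cbind(c(20, 75, 20, 75, 48, 48), c(25, 25, 80, 80, 40, 70))
  dst <- t(A %*% (t(src) - ctr) + ctr + shift)
  pairs <- control_point_pairs(src, dst)
  warp <- mls_affine_warp(sto2$sto2, pairs, alpha = config$mls$alpha,
                          grid_step = config$mls$grid_step)
  mapped <- mls_warp_points(pairs, src, alpha = config$mls$alpha)
  registration <- list(
    landmark_max_residual_px = max(sqrt(rowSums((mapped - dst)^2))),
    warped_valid_fraction = mean(warp$valid_mask))

  fcda_frames <- stats::setNames(lapply(seq_along(zl), function(i) {
    lapply(seq_len(config$fcda$frames_per_zone), function(k) {
      vs <- zone_vessel_phantom(zl[i], config$fcda$fov_radius,
                                seed = seed + 100L * i + k)
      generate_confocal_frame(vs, config$fcda$fov_radius)
    })
  }), zl)
  fcda <- fcda_zone_contrast(fcda_frames,
                             min_elongation = config$fcda$min_elongation,
                             min_area = config$fcda$min_area,
                             blur_sigma = config$fcda$blur_sigma)

  cp <- cohort_params(n_subjects = config$cohort$n_subjects,
                      lcl_noise_sd = config$cohort$lcl_noise_sd,
                      seed = seed + 17L)
  cohort <- generate_cohort(cp)

  model_sto2 <- fit_lcl_model(cohort, "sto2")
  model_fler <- fit_lcl_model(cohort, "fler_slope")
  cv_sto2 <- loo_cv(cohort, "sto2")
  cv_fler <- loo_cv(cohort, "fler_slope")
  err_sto2 <- error_summary(cv_sto2$abs_error, cv_sto2$observed)
  err_fler <- error_summary(cv_fler$abs_error, cv_fler$observed)
  wil <- compare_models_wilcoxon(cv_sto2$abs_error, cv_fler$abs_error)

  correlations <- list(
    sto2_vs_fler = spearman_correlation(cohort$sto2_pct, cohort$fler_slope),
    sto2_vs_lcl = spearman_correlation(cohort$sto2_pct, cohort$lcl_mmol_l),
    fler_vs_lcl = spearman_correlation(cohort$fler_slope, cohort$lcl_mmol_l))

  report <- structure(list(
    seed = seed,
    config_hash = config_hash(unclass(config)),
    zone_stats = zone_stats,
    registration = registration,
    fcda = list(zone_mean = as.list(fcda$zone_mean),
                zone_sd = as.list(fcda$zone_sd)),
    cohort = cohort,
    models = list(sto2 = as.list(coef(model_sto2)),
                  fler_slope = as.list(coef(model_fler))),
    cv_errors = list(sto2 = unclass(err_sto2), fler_slope = unclass(err_fler)),
    wilcoxon = wil,
    correlations = correlations,
    sample_size_r078 = sample_size_correlation(0.78, 0.05, 0.9)
  ), class = "run_report")

  if (!is.null(out_dir)) {
    write_video_tiff(video, file.path(out_dir, "video.tif"))
    write_map_tiff(slope, file.path(out_dir, "slope.tif"))
    write_map_tiff(sto2, file.path(out_dir, "sto2.tif"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Synthetic perfusion experiment (seed", x$seed,
      ", config", x$config_hash, ")\n")
  cat("Per-zone metrics (classified ROIs):\n")
  print(x$zone_stats, row.names = FALSE, digits = 3)
  cat(sprintf("Registration: max landmark residual %.3g px, %.0f%% valid\n",
              x$registration$landmark_max_residual_px,
              100 * x$registration$warped_valid_fraction))
  cat("FCD-A zone means:",
      paste(sprintf("%s %.3g", names(x$fcda$zone_mean),
                    unlist(x$fcda$zone_mean)), collapse = ", "), "\n")
  cat(sprintf("Models: StO2 (a=%.4g, b=%.4g); slope (a=%.4g, b=%.4g)\n",
              x$models$sto2$a, x$models$sto2$b,
              x$models$fler_slope$a, x$models$fler_slope$b))
  cat(sprintf("LOO-CV mean error: StO2 %.3g, slope %.3g mmol/L (Wilcoxon p = %.3g)\n",
              x$cv_errors$sto2$mean, x$cv_errors$fler_slope$mean,
              x$wilcoxon$p.value))
  cat(sprintf("Spearman: StO2~slope %.3f, StO2~LCL %.3f, slope~LCL %.3f\n",
              x$correlations$sto2_vs_fler$rho, x$correlations$sto2_vs_lcl$rho,
              x$correlations$fler_vs_lcl$rho))
  invisible(x)
}

#' Render figures from a run report
#'
#' Writes PNG figures: metric-versus-lactate scatter plots with the fitted
#' exponential curves, and per-zone bar summaries for both modalities.
#'
#' @param report A [run_experiment()] result.
#' @param out_dir Directory for the figures.
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  co <- report$cohort

  scatter <- function(file, x, lcl, systemic, cf, xlab) {
    grDevices::png(file, width = 720, height = 560)
    on.exit(grDevices::dev.off())
    graphics::plot(x, lcl - systemic, pch = 19, xlab = xlab,
                   ylab = "normalized LCL (mmol/L)")
    xx <- seq(min(x), max(x), length.out = 200)
    graphics::lines(xx, exp(-cf$a * xx + cf$b), col = "red3", lwd = 2)
  }
  f1 <- file.path(out_dir, "lcl_vs_sto2.png")
  scatter(f1, co$sto2_pct, co$lcl_mmol_l, co$systemic_lactate_mmol_l,
          report$models$sto2, "StO2 (%)")
  f2 <- file.path(out_dir, "lcl_vs_slope.png")
  scatter(f2, co$fler_slope, co$lcl_mmol_l, co$systemic_lactate_mmol_l,
          report$models$fler_slope, "time-to-peak slope (1/s)")
  paths <- c(paths, f1, f2)

  f3 <- file.path(out_dir, "zone_summary.png")
  grDevices::png(f3, width = 720, height = 560)
  zs <- report$zone_stats
  graphics::par(mfrow = c(1, 2))
  graphics::barplot(zs$sto2_mean, names.arg = zs$zone, main = "StO2 (%)",
                    col = c("forestgreen", "orange", "firebrick"))
  graphics::barplot(zs$slope_mean, names.arg = zs$zone,
                    main = "slope (1/s)",
                    col = c("forestgreen", "orange", "firebrick"))
  grDevices::dev.off()
  paths <- c(paths, f3)
  invisible(paths)
}
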