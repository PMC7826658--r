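#' Zone specification for the synthetic ischemia scene
#'
#' Describes one perfusion zone of the partial-ischemia phantom: its tissue
#' oxygen saturation (StO2) distribution and its indocyanine-green inflow
#' kinetics. Defaults for the three canonical zones are provided by
#' [default_zones()].
#'
#' @param label One of `"vital"`, `"transition"`, `"ischemic"`.
#' @param sto2_mean,sto2_sd StO2 distribution of the zone, in percent.
#' @param inflow_delay Seconds before the fluorescence signal starts rising.
#' @param time_to_peak Seconds (from injection) at which the fluorescence
#'   curve first attains its plateau.
#' @param peak_intensity Plateau fluorescence intensity, arbitrary units.
#' @param lcl_noise_sd Log-scale standard deviation of the multiplicative
#'   noise on generated local capillary lactate.
#' @return An object of class `zone_spec`.
#' @export
zone_spec <- function(label, sto2_mean, sto2_sd, inflow_delay, time_to_peak,
                      peak_intensity, lcl_noise_sd = 0.3) {
  label <- match.arg(label, c("vital", "transition", "ischemic"))
  if (sto2_mean < 0 || sto2_mean > 100)
    stop_perfmap("perfmap_parameter_error", "sto2_mean must lie in [0, 100]")
  if (time_to_peak <= 0)
    stop_perfmap("perfmap_parameter_error", "time_to_peak must be positive")
  if (peak_intensity < 0)
    stop_perfmap("perfmap_parameter_error", "peak_intensity must be >= 0")
  if (inflow_delay < 0 || inflow_delay >= time_to_peak)
    stop_perfmap("perfmap_parameter_error",
                 "inflow_delay must lie in [0, time_to_peak)")
  structure(list(label = label, sto2_mean = sto2_mean, sto2_sd = sto2_sd,
                 inflow_delay = inflow_delay, time_to_peak = time_to_peak,
                 peak_intensity = peak_intensity, lcl_noise_sd = lcl_noise_sd),
            class = "zone_spec")
}

#' Default three-zone parameters of the partial-ischemia phantom
#'
#' StO2 means and standard deviations are the per-ROI values reported for the
#' porcine pancreatic partial-ischemia experiment (76.5 +/- 6.0 percent vital,
#' 48.8 +/- 8.1 transition, 16.5 +/- 4.76 ischemic). Inflow kinetics (delay,
#' time-to-peak, plateau intensity) have no published anchor; the defaults are
#' chosen so that the resulting time-to-peak slopes are ordered
#' vital > transition > ischemic, as observed in vivo.
#'
#' @return Named list of three [zone_spec()] objects.
#' @export
default_zones <- function() {
  list(
    vital      = zone_spec("vital",      76.5, 6.0,  2, 8,  100),
    transition = zone_spec("transition", 48.8, 8.1,  4, 15, 80),
    ischemic   = zone_spec("ischemic",   16.5, 4.76, 8, 30, 30)
  )
}

#' Scene layout for the synthetic surgical field
#'
#' Holds the pixel geometry of the phantom: one binary mask per perfusion
#' zone, a reference-card mask and a field-of-view (valid tissue) mask. All
#' masks are `height x width` logical matrices; zone masks must be pairwise
#' disjoint and disjoint from the reference card.
#'
#' @param height,width Image size in pixels.
#' @param zone_masks Named list of logical matrices (names are zone labels).
#' @param reference_card_mask Logical matrix, nonempty.
#' @param fov_mask Logical matrix marking valid tissue; defaults to the union
#'   of the zone masks.
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(height, width, zone_masks, reference_card_mask,
                         fov_mask = NULL) {
  dims_ok <- function(m) is.matrix(m) && nrow(m) == height && ncol(m) == width
  zone_masks <- lapply(zone_masks, as_mask)
  reference_card_mask <- as_mask(reference_card_mask)
  if (!all(vapply(zone_masks, dims_ok, logical(1))) || !dims_ok(reference_card_mask))
    stop_perfmap("perfmap_invalid_layout", "all masks must be %d x %d matrices",
                 height, width)
  acc <- matrix(0L, height, width)
  for (m in zone_masks) acc <- acc + m
  if (any(acc > 1L))
    stop_perfmap("perfmap_invalid_layout", "zone masks overlap")
  if (any(reference_card_mask & (acc > 0L)))
    stop_perfmap("perfmap_invalid_layout",
                 "reference card overlaps a zone mask")
  if (!any(reference_card_mask))
    stop_perfmap("perfmap_invalid_layout", "reference card mask is empty")
  if (is.null(fov_mask)) fov_mask <- acc > 0L else fov_mask <- as_mask(fov_mask)
  if (!dims_ok(fov_mask))
    stop_perfmap("perfmap_invalid_layout", "fov_mask has wrong dimensions")
  structure(list(height = height, width = width, zone_masks = zone_masks,
                 reference_card_mask = reference_card_mask,
                 fov_mask = fov_mask),
            class = "scene_layout")
}

#' Default scene: three vertical zone bands plus a corner reference card
#'
#' @param height,width Image size in pixels.
#' @param ref_size Side of the square reference card, pixels.
#' @param zones Zone labels, left to right.
#' @return A [scene_layout()].
#' @export
default_scene_layout <- function(height = 96, width = 96, ref_size = 12,
                                 zones = c("vital", "transition", "ischemic")) {
  # reference card occupies the top-left corner; bands start below it
  band_top <- ref_size + 4
  band_w <- width %/% length(zones)
  mk <- function(j) {
    m <- matrix(FALSE, height, width)
    cols <- ((j - 1) * band_w + 1):(if (j == length(zones)) width else j * band_w)
    m[band_top:height, cols] <- TRUE
    m
  }
  zone_masks <- stats::setNames(lapply(seq_along(zones), mk), zones)
  ref <- matrix(FALSE, height, width)
  ref[1:ref_size, 1:ref_size] <- TRUE
  scene_layout(height, width, zone_masks, ref)
}

# Truncated-logistic inflow curve: smooth monotone rise after `delay`,
# plateau (exactly) from `time_to_peak` onwards. The first time the curve
# attains its maximum is time_to_peak by construction.
#' @noRd
inflow_curve <- function(t, delay, time_to_peak, peak) {
  k <- 10 / (time_to_peak - delay)
  t50 <- (delay + time_to_peak) / 2
  L <- 1 / (1 + exp(-k * (t - t50)))
  peak * pmin(L / (1 / (1 + exp(-k * (time_to_peak - t50)))), 1)
}

#' Generate a synthetic fluorescence video stack
#'
#' Builds a `time x height x width` intensity stack in which every pixel of a
#' perfusion zone follows that zone's truncated-logistic indocyanine-green
#' inflow curve, reference-card pixels hold a constant mean intensity, and
#' pixels outside all masks carry background noise only. A single
#' multiplicative `attenuation` factor models distance/illumination loss; the
#' reference-card normalization of the slope computation is designed to
#' cancel exactly this factor.
#'
#' @param layout A [scene_layout()].
#' @param zones Named list of [zone_spec()]s covering the layout's zone names.
#' @param duration Video length in seconds (default 40).
#' @param fps Frames per second (default 25).
#' @param noise_sd Gaussian sensor-noise standard deviation (intensity units).
#' @param ref_intensity Mean reference-card intensity, arbitrary units.
#' @param background_level Mean background intensity outside all masks.
#' @param attenuation Multiplicative scene factor applied to every mean
#'   intensity (tissue, card and background alike).
#' @param seed Optional integer seed; fixed seed gives a bit-identical stack.
#' @return Object of class `fluorescence_video`: list with `frames`
#'   (`time x height x width` array), `fps`, `reference_card_mask`, and
#'   `ground_truth` (per-pixel `t_peak` and `peak` matrices, `NA` off-zone).
#' @export
generate_fluorescence_video <- function(layout, zones = default_zones(),
                                        duration = 40, fps = 25,
                                        noise_sd = 1, ref_intensity = 50,
                                        background_level = 1, attenuation = 1,
                                        seed = NULL) {
  stopifnot(inherits(layout, "scene_layout"))
  if (fps <= 0)
    stop_perfmap("perfmap_parameter_error", "fps must be positive")
  n_frames <- as.integer(round(duration * fps))
  if (n_frames < 2)
    stop_perfmap("perfmap_parameter_error", "duration * fps must be >= 2 frames")
  missing_zones <- setdiff(names(layout$zone_masks), names(zones))
  if (length(missing_zones))
    stop_perfmap("perfmap_parameter_error", "no zone_spec for zone(s): %s",
                 paste(missing_zones, collapse = ", "))
  h <- layout$height; w <- layout$width
  t_sec <- (seq_len(n_frames) - 1) / fps

  frames <- array(background_level * attenuation, dim = c(n_frames, h, w))
  gt_tpeak <- matrix(NA_real_, h, w)
  gt_peak <- matrix(NA_real_, h, w)
  for (lab in names(layout$zone_masks)) {
    z <- zones[[lab]]
    mask <- layout$zone_masks[[lab]]
    curve <- inflow_curve(t_sec, z$inflow_delay, z$time_to_peak,
                          z$peak_intensity) * attenuation
    idx <- which(mask)
    if (length(idx)) {
      # frames is time-major: pixel p occupies frames[, p] in the t x (h*w) view
      dim(frames) <- c(n_frames, h * w)
      frames[, idx] <- curve
      dim(frames) <- c(n_frames, h, w)
      gt_tpeak[idx] <- z$time_to_peak
      gt_peak[idx] <- z$peak_intensity * attenuation
    }
  }
  ref_idx <- which(layout$reference_card_mask)
  dim(frames) <- c(n_frames, h * w)
  frames[, ref_idx] <- ref_intensity * attenuation
  if (noise_sd > 0)
    frames <- frames + with_seed(seed, matrix(stats::rnorm(length(frames), 0, noise_sd),
                                              nrow(frames)))
  dim(frames) <- c(n_frames, h, w)
  structure(list(frames = frames, fps = fps,
                 reference_card_mask = layout$reference_card_mask,
                 ground_truth = list(t_peak = gt_tpeak, peak = gt_peak)),
            class = "fluorescence_video")
}

#' Generate a synthetic StO2 map
#'
#' Per-pixel tissue oxygen saturation drawn from each zone's
#' Normal(sto2_mean, sto2_sd), clipped to `[0, 100]`; pixels outside all
#' zones are flagged invalid.
#'
#' @inheritParams generate_fluorescence_video
#' @return Object of class `sto2_map`: list with `sto2` (matrix, percent) and
#'   `valid_mask`.
#' @export
generate_sto2_map <- function(layout, zones = default_zones(), seed = NULL) {
  stopifnot(inherits(layout, "scene_layout"))
  sto2 <- matrix(NA_real_, layout$height, layout$width)
  valid <- matrix(FALSE, layout$height, layout$width)
  with_seed(seed, {
    for (lab in names(layout$zone_masks)) {
      z <- zones[[lab]]
      idx <- which(layout$zone_masks[[lab]])
      sto2[idx] <- pmin(100, pmax(0, stats::rnorm(length(idx), z$sto2_mean, z$sto2_sd)))
      valid[idx] <- TRUE
    }
  })
  structure(list(sto2 = sto2, valid_mask = valid), class = "sto2_map")
}

#' Generate a synthetic confocal endomicroscopy frame
#'
#' Renders bright tubular vessels of known diameter on a dark background
#' inside a circular field of view, and returns the analytic ground truth
#' (total centerline length, length-weighted mean diameter, and the implied
#' capillary-density index d * L / (pi * r^2)).
#'
#' @param vessels List of vessels; each is a list with `path` (n x 2 matrix
#'   of x,y vertex coordinates, pixels, 1-based) and `diameter` (pixels,
#'   >= 2).
#' @param fov_radius Field-of-view radius in pixels; the frame is a square of
#'   side `2 * fov_radius + 1`.
#' @param contrast Vessel intensity above background (image is in `[0, 1]`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param background Background intensity.
#' @param seed Optional integer seed.
#' @return Object of class `confocal_frame`: `intensity`, `fov_mask`,
#'   `pixel_size`, `ground_truth` (`total_length`, `mean_diameter`,
#'   `fov_area`, `fcda`).
#' @export
generate_confocal_frame <- function(vessels, fov_radius, contrast = 0.75,
                                    noise_sd = 0, background = 0.05,
                                    seed = NULL) {
  side <- 2L * as.integer(fov_radius) + 1L
  cx <- fov_radius + 1
  xs <- matrix(rep(seq_len(side), each = side), side, side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), side, side)  # row index
  fov <- (xs - cx)^2 + (ys - cx)^2 <= fov_radius^2

  seg_len <- 0; wsum_d <- 0
  dist2 <- matrix(Inf, side, side)
  for (v in vessels) {
    if (v$diameter < 2)
      stop_perfmap("perfmap_parameter_error", "vessel diameter must be >= 2 px")
    p <- v$path
    if (any((p[, 1] - cx)^2 + (p[, 2] - cx)^2 > fov_radius^2))
      stop_perfmap("perfmap_parameter_error", "vessel centerline outside FOV")
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      ab <- b - a; L2 <- sum(ab^2)
      L <- sqrt(L2)
      seg_len <- seg_len + L
      wsum_d <- wsum_d + L * v$diameter
      # squared distance from every pixel to segment ab, clamped projection
      tt <- if (L2 == 0) 0 else pmin(1, pmax(0, ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / L2))
      d2 <- (xs - (a[1] + tt * ab[1]))^2 + (ys - (a[2] + tt * ab[2]))^2
      r2 <- (v$diameter / 2)^2
      dist2 <- pmin(dist2, d2 / r2)  # normalized by this vessel's radius
    }
  }
  img <- matrix(background, side, side)
  img[dist2 <= 1] <- background + contrast
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd), side))
  img <- pmin(pmax(img, 0), 1)
  img[!fov] <- 0
  mean_d <- if (seg_len > 0) wsum_d / seg_len else 0
  fov_area <- pi * fov_radius^2
  structure(list(intensity = img, fov_mask = fov, pixel_size = 1,
                 ground_truth = list(total_length = seg_len,
                                     mean_diameter = mean_d,
                                     fov_area = fov_area,
                                     fcda = mean_d * seg_len / fov_area)),
            class = "confocal_frame")
}

#' Random straight-vessel phantom for one perfusion zone
#'
#' Places `n_vessels` non-overlapping straight vessels of equal diameter and
#' total centerline length `total_length` uniformly inside the field of view.
#' The per-zone defaults of [zone_vessel_phantom()] are calibrated so the
#' resulting capillary-density index reproduces the in-vivo zone contrast.
#'
#' @param fov_radius Field-of-view radius, pixels.
#' @param total_length Summed centerline length, pixels.
#' @param diameter Vessel diameter, pixels.
#' @param n_vessels Number of straight vessels.
#' @param seed Optional integer seed.
#' @return List of vessels suitable for [generate_confocal_frame()].
#' @export
make_vessel_phantom <- function(fov_radius, total_length, diameter,
                                n_vessels, seed = NULL) {
  L <- total_length / n_vessels
  cx <- fov_radius + 1
  margin <- diameter + 2
  R_eff <- fov_radius - margin          # centerlines stay this far from rim
  if (R_eff <= L / 2)
    stop_perfmap("perfmap_parameter_error", "vessel too long for FOV")
  jmax <- 0.04                          # per-vessel angle jitter, radians
  clearance <- diameter + 4
  spacing <- clearance + L * sin(jmax) + 2
  with_seed(seed, {
    # capillary beds are roughly co-aligned: one global direction, vessels
    # in parallel lanes with positional and angular jitter
    phi <- stats::runif(1, 0, pi)
    dvec <- c(cos(phi), sin(phi)); pvec <- c(-sin(phi), cos(phi))
    k <- floor(R_eff / spacing)
    offsets <- sample(spacing * seq(-k, k))
    vessels <- list()
    for (o in offsets) {
      if (length(vessels) >= n_vessels) break
      half_chord <- sqrt(max(0, R_eff^2 - o^2))
      n_fit <- floor((2 * half_chord + clearance) / (L + clearance))
      if (n_fit < 1) next
      slack <- (2 * half_chord - n_fit * L - (n_fit - 1) * clearance) / (n_fit + 1)
      u <- -half_chord
      for (j in seq_len(n_fit)) {
        if (length(vessels) >= n_vessels) break
        u <- u + stats::runif(1, 0.2, 1) * slack + L / 2
        ang <- phi + stats::runif(1, -jmax, jmax)
        c0 <- c(cx, cx) + o * pvec + u * dvec
        a <- c0 - L / 2 * c(cos(ang), sin(ang))
        b <- c0 + L / 2 * c(cos(ang), sin(ang))
        vessels[[length(vessels) + 1]] <- list(path = rbind(a, b),
                                               diameter = diameter)
        u <- u + L / 2 + clearance
      }
    }
    if (length(vessels) < n_vessels)
      stop_perfmap("perfmap_parameter_error",
                   "could not place %d non-overlapping vessels of length %.0f",
                   n_vessels, L)
    vessels
  })
}

#' @rdname make_vessel_phantom
#' @param label Zone label; vessel density decreases from vital to ischemic
#'   (defaults calibrated to mean capillary-density indices of roughly
#'   0.26 / 0.247 / 0.122 at `fov_radius = 120`).
#' @export
zone_vessel_phantom <- function(label = c("vital", "transition", "ischemic"),
                                fov_radius = 120, seed = NULL) {
  label <- match.arg(label)
  pars <- switch(label,
    vital      = list(total_length = 1470, n = 20L),
    transition = list(total_length = 1397, n = 20L),
    ischemic   = list(total_length = 690,  n = 10L))
  make_vessel_phantom(fov_radius, pars$total_length, diameter = 8,
                      n_vessels = pars$n, seed = seed)
}

#' Cohort parameters for the synthetic lactate experiment
#'
#' Defaults follow the in-vivo study conditions: six subjects, systemic
#' lactate 1.87 +/- 0.869 mmol/L, and local capillary lactate (LCL) generated
#' from the StO2 model `LCL = exp(-0.0343 * StO2 + 2.72) * exp(eps) + systemic`
#' with log-normal noise. Per-zone StO2 and slope marginals default to the
#' reported per-ROI means and SDs.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param systemic_lactate_mean,systemic_lactate_sd Systemic lactate
#'   distribution, mmol/L.
#' @param model_sto2,model_fler Named vectors `c(a=, b=)` of the generating
#'   exponential models for the StO2 and slope predictors.
#' @param sto2_marginals,fler_marginals 3 x 2 matrices (rows vital,
#'   transition, ischemic; columns mean, sd) of the per-zone predictor draws.
#' @param lcl_noise_sd Log-scale SD of the multiplicative lactate noise.
#' @param seed Integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 6,
                          systemic_lactate_mean = 1.87,
                          systemic_lactate_sd = 0.869,
                          model_sto2 = c(a = 0.0343, b = 2.72),
                          model_fler = c(a = 0.403, b = 2.32),
                          sto2_marginals = rbind(vital = c(76.5, 6.0),
                                                 transition = c(48.8, 8.1),
                                                 ischemic = c(16.5, 4.76)),
                          fler_marginals = rbind(vital = c(6.79, 4.43),
                                                 transition = c(5.67, 4.93),
                                                 ischemic = c(0.94, 0.6)),
                          lcl_noise_sd = 0.3, seed = NULL) {
  if (n_subjects < 2)
    stop_perfmap("perfmap_parameter_error", "n_subjects must be >= 2")
  if (systemic_lactate_mean < 0 || systemic_lactate_sd < 0)
    stop_perfmap("perfmap_parameter_error", "lactate mean/sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 systemic_lactate_mean = systemic_lactate_mean,
                 systemic_lactate_sd = systemic_lactate_sd,
                 model_sto2 = model_sto2, model_fler = model_fler,
                 sto2_marginals = sto2_marginals,
                 fler_marginals = fler_marginals,
                 lcl_noise_sd = lcl_noise_sd, seed = seed),
            class = "cohort_params")
}

#' Generate a synthetic subject cohort
#'
#' Each subject receives one systemic lactate draw and three regions of
#' interest (vital / transition / ischemic) with StO2 and time-to-peak slope
#' draws from the per-zone marginals. Local capillary lactate is generated
#' from the StO2 model: `lcl = exp(-a * sto2 + b) * exp(eps) + systemic`,
#' `eps ~ N(0, lcl_noise_sd)`, so all lactates are positive.
#'
#' @param params A [cohort_params()].
#' @return A data.frame with one row per subject x ROI and columns
#'   `subject_id`, `roi_label`, `sto2_pct`, `fler_slope`, `lcl_mmol_l`,
#'   `systemic_lactate_mmol_l`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  zl <- c("vital", "transition", "ischemic")
  n <- params$n_subjects
  with_seed(params$seed, {
    systemic <- pmax(0.05, stats::rnorm(n, params$systemic_lactate_mean,
                                        params$systemic_lactate_sd))
    rows <- vector("list", n * 3L)
    k <- 0L
    for (s in seq_len(n)) {
      for (z in zl) {
        k <- k + 1L
        sm <- params$sto2_marginals[z, ]
        fm <- params$fler_marginals[z, ]
        sto2 <- min(100, max(0, stats::rnorm(1, sm[1], sm[2])))
        fler <- max(0.01, stats::rnorm(1, fm[1], fm[2]))
        eps <- if (params$lcl_noise_sd > 0)
          stats::rnorm(1, 0, params$lcl_noise_sd) else 0
        a <- params$model_sto2[["a"]]; b <- params$model_sto2[["b"]]
        lcl <- exp(-a * sto2 + b) * exp(eps) + systemic[s]
        rows[[k]] <- data.frame(subject_id = s, roi_label = z,
                                sto2_pct = sto2, fler_slope = fler,
                                lcl_mmol_l = lcl,
                                systemic_lactate_mmol_l = systemic[s])
      }
    }
    do.call(rbind, rows)
  })
}
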