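#' Construct a confocal frame object
#'
#' @param intensity 2-D grayscale matrix in `[0, 1]`.
#' @param fov_mask Logical matrix marking the (circular) field of view.
#' @param pixel_size Physical units per pixel (default 1; the index is then
#'   in pixel units).
#' @return Object of class `confocal_frame`.
#' @export
confocal_frame <- function(intensity, fov_mask, pixel_size = 1) {
  stopifnot(is.matrix(intensity))
  fov_mask <- as_mask(fov_mask)
  if (!any(fov_mask))
    stop_perfmap("perfmap_parameter_error", "FOV mask is empty")
  structure(list(intensity = intensity, fov_mask = fov_mask,
                 pixel_size = pixel_size, ground_truth = NULL),
            class = "confocal_frame")
}

# Zhang-Suen morphological thinning to a 1-px-wide, 8-connected skeleton.
# Vectorized over matrix shifts; iterates until stable.
#' @noRd
thin_mask <- function(mask) {
  m <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  pad <- function(x) {
    out <- matrix(0L, h + 2, w + 2); out[2:(h + 1), 2:(w + 1)] <- x; out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      ctr <- p[2:(h + 1), 2:(w + 1)]
      # neighbors clockwise from north (row - 1)
      P2 <- p[1:h,       2:(w + 1)]; P3 <- p[1:h,       3:(w + 2)]
      P4 <- p[2:(h + 1), 3:(w + 2)]; P5 <- p[3:(h + 2), 3:(w + 2)]
      P6 <- p[3:(h + 2), 2:(w + 1)]; P7 <- p[3:(h + 2), 1:w]
      P8 <- p[2:(h + 1), 1:w];       P9 <- p[1:h,       1:w]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
           (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- ctr == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- ctr == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Segment capillaries as elongated bright structures
#'
#' Operator chain: Gaussian blur, Otsu threshold computed within the field of
#' view, connected-component filtering by elongation (major/minor axis
#' ratio) and area, morphological thinning to a centerline skeleton, and
#' per-skeleton-pixel diameter as twice the Euclidean distance transform of
#' the vessel mask.
#'
#' @param frame A [confocal_frame()].
#' @param min_elongation Minimum major/minor axis ratio kept (default 3).
#' @param min_area Minimum component area in pixels^2 (default 50).
#' @param blur_sigma Gaussian blur sigma, pixels (default 1).
#' @return Object of class `vessel_segmentation`: `vessel_mask`, `skeleton`,
#'   `diameters` (per skeleton pixel, pixels).
#' @export
segment_vessels <- function(frame, min_elongation = 3, min_area = 50,
                            blur_sigma = 1) {
  stopifnot(inherits(frame, "confocal_frame"))
  if (!any(frame$fov_mask))
    stop_perfmap("perfmap_parameter_error", "empty FOV")
  img <- frame$intensity
  blurred <- if (blur_sigma > 0) EBImage::gblur(img, sigma = blur_sigma) else img
  vals <- blurred[frame$fov_mask]
  empty <- function() {
    structure(list(vessel_mask = matrix(FALSE, nrow(img), ncol(img)),
                   skeleton = matrix(FALSE, nrow(img), ncol(img)),
                   diameters = numeric(0)),
              class = "vessel_segmentation")
  }
  if (diff(range(vals)) < 1e-6) return(empty())     # featureless frame
  thr <- EBImage::otsu(EBImage::Image(matrix(pmin(1, pmax(0, vals)), ncol = 1)))
  mask <- frame$fov_mask & blurred > thr
  if (!any(mask)) return(empty())
  lab <- EBImage::bwlabel(mask * 1)
  nobj <- max(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
  areas <- tabulate(lab[lab > 0], nbins = nobj)
  major <- mom[, "m.majoraxis"]
  minor <- major * sqrt(pmax(0, 1 - mom[, "m.eccentricity"]^2))
  elong <- ifelse(minor > 1e-9, major / minor, Inf)
  keep <- which(areas >= min_area & elong >= min_elongation)
  vessel <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (!any(vessel)) return(empty())
  skel <- thin_mask(vessel)
  dm <- EBImage::distmap(vessel * 1)
  structure(list(vessel_mask = vessel, skeleton = skel,
                 diameters = 2 * dm[skel]),
            class = "vessel_segmentation")
}

# Skeleton length: 4-neighbor edges count 1, diagonal edges sqrt(2); a
# diagonal is only counted when neither mediating orthogonal pixel is
# present (otherwise the path is already measured by the two unit edges).
#' @noRd
skeleton_length <- function(sk) {
  h <- nrow(sk); w <- ncol(sk)
  if (!any(sk)) return(0)
  horiz <- sum(sk[, -w] & sk[, -1])
  vert <- sum(sk[-h, ] & sk[-1, ])
  d1 <- sum(sk[-h, -w] & sk[-1, -1] & !(sk[-h, -1] | sk[-1, -w]))
  d2 <- sum(sk[-h, -1] & sk[-1, -w] & !(sk[-h, -w] | sk[-1, -1]))
  horiz + vert + sqrt(2) * (d1 + d2)
}

#' Functional capillary density area index
#'
#' `FCD-A = mean capillary diameter x total vessel length / field-of-view
#' area`: mean diameter is the skeleton-pixel-weighted mean of the local
#' diameters, total length is measured along the skeleton (diagonal steps
#' counted sqrt(2)), and the area is the pixel count of the (round) field of
#' view. An empty segmentation yields 0.
#'
#' @param seg A [segment_vessels()] result.
#' @param fov_mask Logical field-of-view mask, nonempty.
#' @return Object of class `fcda_result`: `mean_diameter`, `total_length`,
#'   `fov_area`, `fcda`.
#' @export
compute_fcda <- function(seg, fov_mask) {
  stopifnot(inherits(seg, "vessel_segmentation"))
  fov_mask <- as_mask(fov_mask)
  if (!any(fov_mask))
    stop_perfmap("perfmap_parameter_error", "FOV mask is empty")
  fov_area <- sum(fov_mask)
  if (!any(seg$skeleton)) {
    return(structure(list(mean_diameter = 0, total_length = 0,
                          fov_area = fov_area, fcda = 0),
                     class = "fcda_result"))
  }
  mean_d <- mean(seg$diameters)
  len <- skeleton_length(seg$skeleton)
  structure(list(mean_diameter = mean_d, total_length = len,
                 fov_area = fov_area, fcda = mean_d * len / fov_area),
            class = "fcda_result")
}

#' Per-zone capillary density contrast
#'
#' Computes the FCD-A index for every frame of each zone and summarizes the
#' per-zone means, SDs and all pairwise mean differences.
#'
#' @param frames_by_zone Named list (`vital`, `transition`, `ischemic`) of
#'   lists of [confocal_frame()]s, at least one frame per zone.
#' @param ... Passed to [segment_vessels()].
#' @return List with `per_frame` (data.frame), `zone_mean`, `zone_sd`,
#'   `pairwise_diff` (matrix of mean differences, row minus column).
#' @export
fcda_zone_contrast <- function(frames_by_zone, ...) {
  need <- c("vital", "transition", "ischemic")
  missing_zones <- setdiff(need, names(frames_by_zone))
  if (length(missing_zones))
    stop_perfmap("perfmap_parameter_error", "missing zone(s): %s",
                 paste(missing_zones, collapse = ", "))
  rows <- list()
  for (z in need) {
    fr <- frames_by_zone[[z]]
    if (!length(fr))
      stop_perfmap("perfmap_parameter_error", "zone '%s' has no frames", z)
    for (i in seq_along(fr)) {
      seg <- segment_vessels(fr[[i]], ...)
      res <- compute_fcda(seg, fr[[i]]$fov_mask)
      rows[[length(rows) + 1]] <- data.frame(
        zone = z, frame = i, mean_diameter_px = res$mean_diameter,
        total_length_px = res$total_length, fov_area_px2 = res$fov_area,
        fcda = res$fcda)
    }
  }
  per_frame <- do.call(rbind, rows)
  zm <- tapply(per_frame$fcda, factor(per_frame$zone, levels = need), mean)
  zs <- tapply(per_frame$fcda, factor(per_frame$zone, levels = need), stats::sd)
  diff_mat <- outer(zm, zm, "-")
  list(per_frame = per_frame, zone_mean = zm, zone_sd = zs,
       pairwise_diff = diff_mat)
}

#' @export
print.fcda_result <- function(x, ...) {
  cat(sprintf("FCD-A: %.4g  (mean diameter %.2f px, length %.1f px, area %d px^2)\n",
              x$fcda, x$mean_diameter, x$total_length, x$fov_area))
  invisible(x)
}
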