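#' Landmark pairs controlling a moving-least-squares warp
#'
#' @param src,dst n x 2 matrices of paired (x, y) coordinates, sub-pixel,
#'   1-based. At least 3 pairs; source points pairwise distinct.
#' @return Object of class `control_point_pairs`.
#' @export
control_point_pairs <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 2 || ncol(dst) != 2 || nrow(src) != nrow(dst))
    stop_perfmap("perfmap_parameter_error", "src and dst must be paired n x 2 matrices")
  if (nrow(src) < 3)
    stop_perfmap("perfmap_parameter_error", "need at least 3 landmark pairs")
  if (anyDuplicated(round(src, 8)))
    stop_perfmap("perfmap_parameter_error", "source landmarks must be distinct")
  structure(list(src = src, dst = dst), class = "control_point_pairs")
}

#' Read landmark pairs from CSV
#'
#' Expects columns `x_src,y_src,x_dst,y_dst` in pixel units.
#' @param path CSV file path.
#' @return A [control_point_pairs()].
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  control_point_pairs(cbind(d$x_src, d$y_src), cbind(d$x_dst, d$y_dst))
}

# Affine moving-least-squares evaluation: for each evaluation point v the
# affine map A_v minimizing sum_i w_i |A_v(p_i) - q_i|^2 with weights
# w_i = 1 / |p_i - v|^(2 alpha) is applied to v. Exactly interpolates the
# landmarks in the w -> Inf limit; points within snap_radius of a landmark
# take the landmark's displacement directly.
#' @noRd
mls_affine_points <- function(src, dst, pts, alpha = 1, snap_radius = 0.5) {
  n <- nrow(src); m <- nrow(pts)
  out <- matrix(NA_real_, m, 2)
  d2 <- outer(pts[, 1], src[, 1], "-")^2 + outer(pts[, 2], src[, 2], "-")^2
  d2 <- pmax(d2, 1e-16)                       # distance floored at 1e-8 px
  wts <- 1 / d2^alpha                          # m x n
  snap <- apply(d2, 1, function(r) {
    j <- which.min(r)
    if (sqrt(r[j]) <= snap_radius) j else NA_integer_
  })
  for (i in seq_len(m)) {
    if (!is.na(snap[i])) {
      j <- snap[i]
      out[i, ] <- pts[i, ] + (dst[j, ] - src[j, ])
      next
    }
    w <- wts[i, ]
    sw <- sum(w)
    pstar <- colSums(w * src) / sw
    qstar <- colSums(w * dst) / sw
    ph <- sweep(src, 2, pstar)                 # n x 2, centered sources
    qh <- sweep(dst, 2, qstar)
    M1 <- crossprod(ph, w * ph)                # sum w_i ph_i ph_i^T (2 x 2)
    M2 <- crossprod(ph, w * qh)
    M <- tryCatch(solve(M1, M2), error = function(e)
      stop_perfmap("perfmap_degenerate_configuration",
                   "source landmarks are collinear (singular MLS system)"))
    out[i, ] <- (pts[i, ] - pstar) %*% M + qstar
  }
  out
}

#' Evaluate the moving-least-squares map at arbitrary points
#'
#' Maps points from the source-landmark frame to the target-landmark frame.
#' Landmarks map (within numerical tolerance) onto their partners; a
#' globally affine set of pairs is reproduced exactly.
#'
#' @param pairs A [control_point_pairs()].
#' @param pts m x 2 matrix of (x, y) points to map.
#' @param alpha Weight falloff exponent (weights `1/d^(2*alpha)`), > 0.
#' @return m x 2 matrix of mapped points.
#' @export
mls_warp_points <- function(pairs, pts, alpha = 1) {
  stopifnot(inherits(pairs, "control_point_pairs"))
  if (alpha <= 0)
    stop_perfmap("perfmap_parameter_error", "alpha must be positive")
  mls_affine_points(pairs$src, pairs$dst, as.matrix(pts), alpha)
}

# Bilinear sampling of img at sub-pixel (x, y) locations; NA outside.
#' @noRd
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  ok <- x >= 1 - 1e-9 & y >= 1 - 1e-9 & x <= w + 1e-9 & y <= h + 1e-9
  # clamp so that exact-edge coordinates stay inside; mask afterwards
  xc <- pmin(pmax(floor(x), 1), w - 1); yc <- pmin(pmax(floor(y), 1), h - 1)
  fx <- x - xc; fy <- y - yc
  v00 <- img[cbind(yc, xc)];     v01 <- img[cbind(yc, xc + 1)]
  v10 <- img[cbind(yc + 1, xc)]; v11 <- img[cbind(yc + 1, xc + 1)]
  val <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  val[!ok] <- NA_real_
  val
}

#' Warp an image with affine moving least squares
#'
#' Deforms a static map (e.g. an StO2 image) onto the target frame defined by
#' landmark correspondences, so that source landmark `p_i` lands on target
#' landmark `q_i`. The dense displacement field is the inverse MLS map
#' (target to source), evaluated on a coarse grid every `grid_step` pixels
#' and bilinearly upsampled; the image is then resampled bilinearly. Target
#' pixels that fall outside the source image are flagged invalid.
#'
#' @param image 2-D numeric matrix (the moving image).
#' @param pairs A [control_point_pairs()] with `src` in `image` coordinates
#'   and `dst` in target coordinates.
#' @param alpha Weight falloff exponent, > 0.
#' @param out_dim `c(height, width)` of the target grid; defaults to
#'   `dim(image)`.
#' @param grid_step Coarse-grid spacing (pixels) for the dense field.
#' @return Object of class `mls_warp`: `image` (warped), `valid_mask`,
#'   `field` (height x width x 2 array of x/y source coordinates for every
#'   target pixel).
#' @export
mls_affine_warp <- function(image, pairs, alpha = 1, out_dim = dim(image),
                            grid_step = 4) {
  stopifnot(is.matrix(image), inherits(pairs, "control_point_pairs"))
  if (alpha <= 0)
    stop_perfmap("perfmap_parameter_error", "alpha must be positive")
  h <- out_dim[1]; w <- out_dim[2]
  # inverse map: control points taken target -> source
  gx <- unique(c(seq(1, w, by = grid_step), w))
  gy <- unique(c(seq(1, h, by = grid_step), h))
  gpts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  gsrc <- mls_affine_points(pairs$dst, pairs$src, gpts, alpha)
  cx <- matrix(gsrc[, 1], length(gy), length(gx))
  cy <- matrix(gsrc[, 2], length(gy), length(gx))
  # bilinear upsample of the coarse field onto the full grid
  up <- function(cm) {
    # interpolate along x (columns) then y (rows)
    fullx <- t(apply(cm, 1, function(r) stats::approx(gx, r, xout = seq_len(w))$y))
    apply(fullx, 2, function(cl) stats::approx(gy, cl, xout = seq_len(h))$y)
  }
  sx <- up(cx); sy <- up(cy)
  vals <- bilinear_sample(image, as.vector(sx), as.vector(sy))
  warped <- matrix(vals, h, w)
  valid <- !is.na(warped)
  field <- array(c(sx, sy), dim = c(h, w, 2))
  structure(list(image = warped, valid_mask = valid, field = field,
                 pairs = pairs, alpha = alpha),
            class = "mls_warp")
}

#' Pseudo-color rendering of a scalar map
#'
#' @param values Numeric matrix.
#' @param valid_mask Logical matrix; invalid pixels are rendered black.
#' @param palette Color palette name passed to [grDevices::hcl.colors()].
#' @param limits Value range mapped onto the palette; defaults to the data
#'   range over valid pixels.
#' @return height x width x 3 RGB array in `[0, 1]`.
#' @export
pseudo_color <- function(values, valid_mask = NULL, palette = "Viridis",
                         limits = NULL) {
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  if (is.null(limits)) limits <- range(values[valid_mask])
  cols <- grDevices::hcl.colors(256, palette)
  idx <- pmin(256, pmax(1, 1 + floor(255 * (values - limits[1]) /
                                       max(limits[2] - limits[1], 1e-12))))
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  out <- array(0, dim = c(nrow(values), ncol(values), 3))
  for (k in 1:3) {
    ch <- matrix(rgb[k, ], nrow(values), ncol(values))
    ch[!valid_mask] <- 0
    out[, , k] <- ch
  }
  out
}

#' Alpha-blend a pseudo-colored map onto a base frame
#'
#' The enhanced-reality composite: `opacity * map + (1 - opacity) * base` on
#' valid map pixels, base passthrough elsewhere.
#'
#' @param base_frame Grayscale matrix or RGB array.
#' @param map_rgb RGB array from [pseudo_color()] (same height/width).
#' @param opacity Blend fraction in `[0, 1]`.
#' @param valid_mask Logical matrix; defaults to all pixels.
#' @return RGB array.
#' @export
overlay <- function(base_frame, map_rgb, opacity = 0.5, valid_mask = NULL) {
  if (opacity < 0 || opacity > 1)
    stop_perfmap("perfmap_parameter_error", "opacity must lie in [0, 1]")
  if (is.matrix(base_frame))
    base_frame <- array(rep(base_frame, 3), dim = c(dim(base_frame), 3))
  if (!identical(dim(base_frame)[1:2], dim(map_rgb)[1:2]))
    stop_perfmap("perfmap_dimension_error", "base and map shapes differ")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, dim(map_rgb)[1], dim(map_rgb)[2])
  out <- base_frame
  for (k in 1:3) {
    b <- base_frame[, , k]; m <- map_rgb[, , k]
    b[valid_mask] <- opacity * m[valid_mask] + (1 - opacity) * b[valid_mask]
    out[, , k] <- b
  }
  out
}
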