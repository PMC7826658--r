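# Shared fixture builders; everything is generated in code.

# Minimal scene: one zone band plus a reference card, arbitrary size.
one_zone_layout <- function(height = 24, width = 24, ref_size = 6,
                            label = "vital") {
  zone <- matrix(FALSE, height, width)
  zone[(ref_size + 3):height, ] <- TRUE
  ref <- matrix(FALSE, height, width)
  ref[1:ref_size, 1:ref_size] <- TRUE
  scene_layout(height, width, stats::setNames(list(zone), label), ref)
}

# Noise-free single-zone video with known kinetics.
noise_free_video <- function(time_to_peak = 10, peak = 100, ref = 50,
                             duration = 40, fps = 25, delay = 2,
                             height = 16, width = 16) {
  layout <- one_zone_layout(height, width)
  zones <- list(vital = zone_spec("vital", 76.5, 6, delay, time_to_peak, peak))
  generate_fluorescence_video(layout, zones, duration = duration, fps = fps,
                              noise_sd = 0, ref_intensity = ref)
}

# Analytic vessel mask for a straight segment (used for segmentation F1).
segment_mask <- function(a, b, diameter, side) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- matrix(rep(seq_len(side), times = side), side, side)
  ab <- b - a; L2 <- sum(ab^2)
  tt <- pmin(1, pmax(0, ((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / L2))
  d2 <- (xs - (a[1] + tt * ab[1]))^2 + (ys - (a[2] + tt * ab[2]))^2
  d2 <= (diameter / 2)^2
}

# Independent per-pixel slope computation: a plain loop re-deriving
# baseline, moving average, first-max and slope with its own arithmetic.
brute_force_slope <- function(video, smooth_window = 5, min_delta = 0.02,
                              baseline_frames = 5) {
  d <- dim(video$frames)
  out <- matrix(NA_real_, d[2], d[3])
  valid <- matrix(FALSE, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      r <- time_to_peak(video$frames[, i, j], video$fps, smooth_window,
                        min_delta, baseline_frames)
      if (r$valid) {
        out[i, j] <- (r$i_peak - r$i_baseline) / r$t_peak
        valid[i, j] <- TRUE
      }
    }
  }
  list(slope = out, valid = valid)
}
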