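test_that("noise-free inflow curves plateau exactly at the configured time-to-peak", {
  fps <- 25
  v <- noise_free_video(time_to_peak = 10, peak = 100, ref = 50, fps = fps)
  layout <- one_zone_layout(16, 16)
  zone_idx <- which(layout$zone_masks$vital)
  nt <- dim(v$frames)[1]
  fm <- v$frames
  dim(fm) <- c(nt, 16 * 16)
  peak_frame <- 10 * fps + 1  # frame 0 is injection time
  for (p in zone_idx[c(1, 25, length(zone_idx))]) {
    curve <- fm[, p]
    expect_equal(which(curve == max(curve))[1], peak_frame)
    expect_equal(max(curve), 100)
    expect_true(all(diff(curve[1:peak_frame]) > 0))            # monotone rise
    expect_true(all(curve[peak_frame:nt] == 100))              # plateau
  }
  # reference card constant across frames
  ref_idx <- which(v$reference_card_mask)
  expect_true(all(fm[, ref_idx] == 50))
})

test_that("video generation is deterministic under a fixed seed and validates input", {
  layout <- default_scene_layout(48, 48, ref_size = 8)
  a <- generate_fluorescence_video(layout, duration = 4, fps = 10, seed = 7)
  b <- generate_fluorescence_video(layout, duration = 4, fps = 10, seed = 7)
  expect_identical(a$frames, b$frames)
  c2 <- generate_fluorescence_video(layout, duration = 4, fps = 10, seed = 8)
  expect_false(identical(a$frames, c2$frames))

  expect_error(generate_fluorescence_video(layout, fps = 0),
               class = "perfmap_parameter_error")
  expect_error(generate_fluorescence_video(layout, duration = 0.05, fps = 10),
               class = "perfmap_parameter_error")
  # overlapping zone masks rejected at layout construction
  m <- matrix(TRUE, 8, 8)
  expect_error(scene_layout(8, 8, list(vital = m, ischemic = m),
                            reference_card_mask = m),
               class = "perfmap_invalid_layout")
})

test_that("slower ischemic kinetics yield a smaller slope than vital (scalar oracle)", {
  fps <- 25
  mk <- function(ttp, peak) noise_free_video(ttp, peak, ref = 50, fps = fps,
                                             delay = 2, height = 16, width = 16)
  v_vital <- mk(8, 100); v_isch <- mk(30, 100)
  # independent scalar calculation straight from the stored curves
  slope_of <- function(v) {
    curve <- v$frames[, 12, 4] / 50         # reference-normalized by hand
    peak <- max(curve)
    t_peak <- (which(curve == peak)[1] - 1) / fps
    (peak - curve[1]) / t_peak
  }
  expect_gt(slope_of(v_vital) / slope_of(v_isch), 1)
})

test_that("StO2 map reproduces configured zone distributions", {
  layout <- one_zone_layout(60, 60)
  # degenerate sd: exact means
  z0 <- list(vital = zone_spec("vital", 42, 0, 2, 8, 100))
  m0 <- generate_sto2_map(layout, z0, seed = 1)
  expect_true(all(m0$sto2[layout$zone_masks$vital] == 42))
  expect_false(any(m0$valid_mask[!layout$zone_masks$vital]))

  # default three-zone parameters: means within 3 SEM
  big <- default_scene_layout(120, 120, ref_size = 10)
  m <- generate_sto2_map(big, seed = 42)
  zones <- default_zones()
  for (lab in names(big$zone_masks)) {
    vals <- m$sto2[big$zone_masks[[lab]]]
    sem <- zones[[lab]]$sto2_sd / sqrt(length(vals))
    expect_lt(abs(mean(vals) - zones[[lab]]$sto2_mean), 3 * sem + 0.05)
  }
  expect_identical(generate_sto2_map(big, seed = 42)$sto2, m$sto2)
})

test_that("confocal frame ground truth follows closed-form geometry", {
  # no vessels: flat background, zero ground truth
  f0 <- generate_confocal_frame(list(), fov_radius = 40)
  expect_equal(f0$ground_truth$total_length, 0)
  expect_true(all(f0$intensity[f0$fov_mask] == f0$intensity[f0$fov_mask][1]))

  # one straight vessel: analytic index d * L / (pi r^2)
  r <- 120
  cx <- r + 1
  v1 <- list(list(path = rbind(c(cx - 50, cx), c(cx + 50, cx)), diameter = 6))
  f1 <- generate_confocal_frame(v1, r)
  expect_equal(f1$ground_truth$total_length, 100)
  expect_equal(f1$ground_truth$mean_diameter, 6)
  expect_equal(f1$ground_truth$fcda, 6 * 100 / (pi * r^2))

  # two disjoint vessels: lengths add
  v2 <- c(v1, list(list(path = rbind(c(cx, cx - 60), c(cx, cx - 20)),
                        diameter = 4)))
  f2 <- generate_confocal_frame(v2, r)
  expect_equal(f2$ground_truth$total_length, 140)

  # centerline outside the field of view is rejected
  bad <- list(list(path = rbind(c(1, 1), c(2 * r, 2 * r)), diameter = 4))
  expect_error(generate_confocal_frame(bad, r),
               class = "perfmap_parameter_error")
})

test_that("cohort generator emits 3 ROIs per subject with self-consistent lactates", {
  co <- generate_cohort(cohort_params(n_subjects = 6, seed = 3))
  expect_equal(nrow(co), 18)
  expect_equal(as.vector(table(co$subject_id)), rep(3L, 6))
  expect_true(all(co$lcl_mmol_l > 0))

  # zero noise: the generating model predicts every record exactly
  co0 <- generate_cohort(cohort_params(n_subjects = 5, lcl_noise_sd = 0, seed = 4))
  pred <- predict_lcl(list(a = 0.0343, b = 2.72), co0$sto2_pct,
                      co0$systemic_lactate_mmol_l)
  expect_equal(pred, co0$lcl_mmol_l, tolerance = 1e-12)

  # large cohort: rank correlation StO2 ~ LCL negative (rank-based oracle)
  big <- generate_cohort(cohort_params(n_subjects = 200, seed = 5))
  expect_lt(stats::cor(big$sto2_pct, big$lcl_mmol_l, method = "spearman"), 0)

  expect_error(cohort_params(n_subjects = 1), class = "perfmap_parameter_error")
})

test_that("cohort per-zone StO2 marginals converge to configured means", {
  co <- generate_cohort(cohort_params(n_subjects = 400, seed = 11))
  cp <- cohort_params()
  for (z in c("vital", "transition", "ischemic")) {
    vals <- co$sto2_pct[co$roi_label == z]
    sem <- cp$sto2_marginals[z, 2] / sqrt(length(vals))
    expect_lt(abs(mean(vals) - cp$sto2_marginals[z, 1]), 3 * sem + 0.1)
  }
})
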