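# File interchange. TIFF samples are stored scaled to [0, 1]; the scale
# factor and metadata travel in a JSON sidecar next to the image, so stacks
# and maps round-trip losslessly up to float precision.

#' Write / read a fluorescence video stack as multi-page TIFF
#'
#' One page per frame, 32-bit samples scaled by the stack maximum; `fps`,
#' scale and mask travel in a JSON sidecar (`<path>.json`).
#'
#' @param video A `fluorescence_video`.
#' @param path Output TIFF path.
#' @return `path`, invisibly. `read_video_tiff()` returns the restored
#'   `fluorescence_video`.
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "fluorescence_video"))
  nt <- dim(video$frames)[1]
  lo <- min(video$frames); hi <- max(video$frames)
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(seq_len(nt), function(t) (video$frames[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(fps = video$fps, offset = lo, scale = scale,
               reference_card = which(video$reference_card_mask),
               dim = dim(video$frames))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- meta$dim
  frames <- array(0, dim = d)
  for (t in seq_len(d[1]))
    frames[t, , ] <- pages[[t]] * meta$scale + meta$offset
  mask <- matrix(FALSE, d[2], d[3])
  mask[meta$reference_card] <- TRUE
  fluorescence_video(frames, meta$fps, mask)
}

#' Write / read a scalar map (slope or StO2) as TIFF with sidecar
#'
#' @param map A `perf_slope_map` or `sto2_map`.
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_map_tiff()` returns a list with `values`
#'   and `valid_mask`.
#' @export
write_map_tiff <- function(map, path) {
  vals <- if (inherits(map, "perf_slope_map")) map$slope else map$sto2
  v <- vals; v[!map$valid_mask] <- 0
  lo <- min(v); hi <- max(v)
  scale <- max(hi - lo, 1e-12)
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            valid = which(map$valid_mask),
                            dim = dim(vals)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- img * meta$scale + meta$offset
  mask <- matrix(FALSE, meta$dim[1], meta$dim[2])
  mask[meta$valid] <- TRUE
  vals[!mask] <- NA_real_
  list(values = vals, valid_mask = mask)
}

#' Write / read a cohort table as CSV
#'
#' Columns: `subject_id, roi_label, sto2_pct, fler_slope, lcl_mmol_l,
#' systemic_lactate_mmol_l`.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_label", "sto2_pct", "fler_slope",
            "lcl_mmol_l", "systemic_lactate_mmol_l")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_perfmap("perfmap_parameter_error", "cohort CSV missing column(s): %s",
                 paste(miss, collapse = ", "))
  d
}
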