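#' Discard short cell and junction tracks
#'
#' Cell tracks with fewer than `min_cell_frames` observations and junction
#' tracks with fewer than `min_junction_frames` observations are removed
#' (defaults: 30 and 15 frames). The counts of removed tracks are attached
#' as the `filter_log` attribute and reported via `message()`.
#'
#' @param dataset A [tracking_dataset()].
#' @param min_cell_frames,min_junction_frames Minimum track lengths kept.
#' @param quiet Suppress the log message.
#' @return The filtered dataset.
#' @export
filter_tracks <- function(dataset, min_cell_frames = 30,
                          min_junction_frames = 15, quiet = FALSE) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  log <- c(cells_removed = 0L, junctions_removed = 0L)
  drop_short <- function(df, id, min_n) {
    keep <- df |>
      dplyr::group_by(.data$movie, .data[[id]]) |>
      dplyr::filter(dplyr::n() >= min_n) |>
      dplyr::ungroup()
    n_before <- dplyr::n_distinct(df[c("movie", id)])
    n_after <- dplyr::n_distinct(keep[c("movie", id)])
    list(df = keep, removed = n_before - n_after)
  }
  if (!is.null(dataset$cell_surfaces)) {
    res <- drop_short(dataset$cell_surfaces, "track_id_cells", min_cell_frames)
    dataset$cell_surfaces <- res$df
    log["cells_removed"] <- res$removed
  }
  if (!is.null(dataset$junctions)) {
    res <- drop_short(dataset$junctions, "track_id_junctions", min_junction_frames)
    dataset$junctions <- res$df
    log["junctions_removed"] <- res$removed
  }
  if (!quiet) {
    message(sprintf("filter_tracks: removed %d cell track(s) (< %d frames), %d junction track(s) (< %d frames)",
                    log["cells_removed"], min_cell_frames,
                    log["junctions_removed"], min_junction_frames))
  }
  attr(dataset, "filter_log") <- log
  dataset
}

#' Centered moving-window smoothing of a track series
#'
#' Each frame's smoothed value is the mean of the usable (non-missing)
#' values in a centered window of `window` frames (default 7: the frame
#' itself plus 3 on each side). At track ends the window is truncated to
#' the available frames rather than dropping frames. Missing input values
#' contribute nothing and remain missing in the output.
#'
#' @param values Numeric vector, one entry per consecutive frame; `NA`
#'   marks masked/missing frames.
#' @param window Odd positive window width in frames.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' smooth_series(c(0, 1, 2, 3, 4, 5, 6, 7)) # first entry mean(0:3) = 1.5
smooth_series <- function(values, window = 7) {
  if (length(window) != 1 || window < 1 || window %% 2 != 1) {
    abort_constrictr("window must be an odd positive integer",
                     "constrictr_parameter_error")
  }
  n <- length(values)
  if (n == 0) return(values)
  half <- (window - 1) / 2
  usable <- !is.na(values)
  v0 <- ifelse(usable, values, 0)
  sums <- numeric(n); counts <- numeric(n)
  for (k in -half:half) {
    idx <- seq_len(n) + k
    ok <- idx >= 1 & idx <= n
    sums[ok] <- sums[ok] + v0[idx[ok]]
    counts[ok] <- counts[ok] + usable[idx[ok]]
  }
  out <- ifelse(counts > 0, sums / counts, NA_real_)
  out[!usable] <- NA_real_
  out
}

#' Standardize a track series to mean 0, s.d. 1
#'
#' Mean-centers the usable values of one track and divides by their sample
#' standard deviation (n − 1 denominator, as R's `scale()` uses), so the
#' series is measured in standard deviations of that track. Statistics are
#' computed over usable (non-missing) frames only; missing frames stay
#' missing. Tracks with fewer than 2 usable frames or zero spread are
#' degenerate: the result is all-missing with attribute `degenerate = TRUE`
#' (never a division by zero).
#'
#' @param values Numeric vector for one track.
#' @return Standardized numeric vector; attribute `degenerate` is `TRUE`
#'   for constant or too-short tracks.
#' @export
standardize_series <- function(values) {
  usable <- !is.na(values)
  n <- sum(usable)
  if (n < 2) {
    out <- rep(NA_real_, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mu <- mean(values[usable])
  s <- stats::sd(values[usable])
  if (!is.finite(s) || s == 0) {
    out <- rep(NA_real_, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - mu) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Mask anomalous frame ranges in the fluorescence channels
#'
#' Sets the raw fluorescence variables (never the geometry) to missing over
#' the configured frame ranges of the matching movie, before smoothing and
#' standardization. Tracks are not split: cells are tracked through the
#' anomaly and their geometric measurements retained.
#'
#' @param dataset A [tracking_dataset()].
#' @param config An [embryo_config()] or a list of them.
#' @return The dataset with fluorescence values masked.
#' @export
mask_frames <- function(dataset, config) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  configs <- if (inherits(config, "embryo_config")) list(config) else config
  for (cfg in configs) {
    stopifnot(inherits(cfg, "embryo_config"))
    for (r in cfg$masked_frame_ranges) {
      if (!is.null(dataset$cell_surfaces)) {
        cs <- dataset$cell_surfaces
        hit <- cs$movie == cfg$movie & cs$minute >= r[1] & cs$minute <= r[2]
        for (col in intersect(cell_fluor_cols, names(cs))) {
          cs[[col]][hit] <- NA_real_
        }
        dataset$cell_surfaces <- cs
      }
      if (!is.null(dataset$junctions)) {
        jx <- dataset$junctions
        hit <- jx$movie == cfg$movie & jx$minute >= r[1] & jx$minute <= r[2]
        for (col in intersect(junction_fluor_cols, names(jx))) {
          jx[[col]][hit] <- NA_real_
        }
        dataset$junctions <- jx
      }
    }
  }
  dataset
}

#' Convert pixel measurements to microns
#'
#' @param value_px Numeric value(s) in pixels (length) or square pixels
#'   (area).
#' @param kind `"length"` or `"area"`.
#' @param config An [embryo_config()] or a positive `microns_per_pixel`
#'   scalar.
#' @return Value in µm (length) or µm² (area).
#' @export
to_microns <- function(value_px, kind = c("length", "area"), config) {
  kind <- match.arg(kind)
  s <- if (inherits(config, "embryo_config")) config$microns_per_pixel else as.numeric(config)
  if (!is.finite(s) || s <= 0) {
    abort_constrictr("microns_per_pixel must be positive", "constrictr_config_error")
  }
  if (kind == "length") value_px * s else value_px * s^2
}

# apply smooth + standardize to one column within track groups
process_column <- function(df, id_cols, raw, smoothed = NULL, standardized = NULL,
                           window = 7) {
  if (!raw %in% names(df)) return(df)
  df <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::arrange(.data$minute, .by_group = TRUE)
  if (!is.null(smoothed)) {
    df <- dplyr::mutate(df, !!smoothed := smooth_series(.data[[raw]], window))
  }
  if (!is.null(standardized)) {
    src <- smoothed %||% raw
    df <- dplyr::mutate(
      df, !!standardized := as.numeric(standardize_series(.data[[src]]))
    )
  }
  dplyr::ungroup(df)
}

#' Run the full per-track preprocessing pipeline
#'
#' Applies, in this fixed order: anomaly-frame masking of fluorescence
#' ([mask_frames()]), short-track filtering ([filter_tracks()]), 7-frame
#' smoothing of every raw variable, unit conversion of areas and lengths to
#' microns, junction length z-correction and orientation (when vertex and
#' z columns are present), and per-track standardization. Populates all
#' `*_smoothed` / `*_standardized` dictionary columns.
#'
#' @param dataset A [tracking_dataset()] with raw measurements.
#' @param config An [embryo_config()] or list of them (one per movie).
#' @param window Smoothing window in frames (odd; default 7).
#' @param min_cell_frames,min_junction_frames Track-length filters.
#' @param quiet Suppress log messages.
#' @return The dataset with derived columns filled in.
#' @export
preprocess_tables <- function(dataset, config, window = 7,
                              min_cell_frames = 30, min_junction_frames = 15,
                              quiet = FALSE) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  configs <- if (inherits(config, "embryo_config")) list(config) else config
  names(configs) <- vapply(configs, function(c) c$movie, "")
  dataset <- mask_frames(dataset, configs)
  dataset <- filter_tracks(dataset, min_cell_frames, min_junction_frames,
                           quiet = quiet)
  scale_of <- function(movie) {
    cfg <- configs[[movie]]
    if (is.null(cfg)) {
      abort_constrictr(sprintf("no embryo_config for movie '%s'", movie),
                       "constrictr_config_error")
    }
    cfg$microns_per_pixel
  }
  cs <- dataset$cell_surfaces
  if (!is.null(cs) && nrow(cs) > 0) {
    ids <- c("movie", "track_id_cells")
    cs <- process_column(cs, ids, "apical_area_pixels",
                         "apical_area_pixels_smoothed", NULL, window)
    if ("apical_area_pixels_smoothed" %in% names(cs)) {
      s <- unname(vapply(cs$movie, scale_of, 0))
      cs$apical_area_micron_smoothed <- cs$apical_area_pixels_smoothed * s^2
      cs <- process_column(cs, ids, "apical_area_pixels_smoothed",
                           NULL, "apical_area_standardized", window)
    }
    for (v in c("medial_actin", "junctional_actin",
                "medial_Ncadherin", "junctional_Ncadherin")) {
      cs <- process_column(cs, ids, v, paste0(v, "_smoothed"),
                           paste0(v, "_standardized"), window)
    }
    for (v in c("medial_memBFP", "junctional_memBFP")) {
      cs <- process_column(cs, ids, v, paste0(v, "_smoothed"), NULL, window)
    }
    dataset$cell_surfaces <- cs
  }
  jx <- dataset$junctions
  if (!is.null(jx) && nrow(jx) > 0) {
    ids <- c("movie", "track_id_junctions")
    if ("length_px" %in% names(jx)) {
      s <- unname(vapply(jx$movie, scale_of, 0))
      jx$length_micron <- jx$length_px * s
    }
    if (all(c("length_micron", "delta_z_micron") %in% names(jx))) {
      jx$length_corrected <- corrected_length(jx$length_micron, jx$delta_z_micron)
    }
    if (all(c("vx_1_x", "vx_1_y", "vx_2_x", "vx_2_y") %in% names(jx)) &&
        !"orientation" %in% names(jx)) {
      ap <- vapply(jx$movie, function(m) configs[[m]]$ap_axis_angle_deg, 0)
      jx$orientation <- junction_orientation(jx$vx_1_x, jx$vx_1_y,
                                             jx$vx_2_x, jx$vx_2_y, ap)
    }
    if ("length_corrected" %in% names(jx)) {
      jx <- process_column(jx, ids, "length_corrected",
                           "length_smooth", "length_standardized", window)
    }
    jx <- process_column(jx, ids, "actin", "actin_smooth",
                         "actin_standardized", window)
    jx <- process_column(jx, ids, "Ncadherin", "Ncadherin_smooth",
                         "Ncadherin_standardized", window)
    dataset$junctions <- jx
  }
  attr(dataset, "preprocess_params") <- list(
    order = c("mask", "filter", "smooth", "convert", "standardize"),
    window = window, min_cell_frames = min_cell_frames,
    min_junction_frames = min_junction_frames
  )
  dataset
}
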