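#' Per-embryo calibration and annotation
#'
#' Holds the calibration every embryo-level correction needs: the pixel size,
#' the confocal z-step, the image-frame angle of the embryo's
#' anteroposterior (AP) axis, an optional membrane-BFP genotype threshold,
#' frame ranges whose fluorescence must be masked (imaging anomalies), and
#' manual genotype overrides for cells along the mosaic interface.
#'
#' @param movie Embryo/movie identifier.
#' @param region `"anterior"` or `"posterior"`.
#' @param microns_per_pixel Positive pixel size, µm/px.
#' @param z_step_micron Positive z-step between confocal slices, µm.
#' @param ap_axis_angle_deg Image-frame angle of the AP axis in degrees
#'   (x rightward, y downward). The mediolateral (ML) axis is this angle
#'   minus 90°. Default 90 (AP = image vertical).
#' @param bfp_threshold Optional manual membrane-BFP threshold separating
#'   control from crispant cells; when `NULL` an automatic bimodal split is
#'   used by [call_genotype()].
#' @param masked_frame_ranges List of inclusive `c(start, end)` integer frame
#'   ranges whose fluorescence values are discarded.
#' @param genotype_overrides Named list/character vector mapping
#'   `track_id_cells` to `"control"` or `"shroom3 crispant"`.
#' @return An `embryo_config` object.
#' @export
embryo_config <- function(movie, region = c("anterior", "posterior"),
                          microns_per_pixel = 1, z_step_micron = 1,
                          ap_axis_angle_deg = 90, bfp_threshold = NULL,
                          masked_frame_ranges = list(),
                          genotype_overrides = list()) {
  region <- match.arg(region)
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0) {
    abort_constrictr("microns_per_pixel must be positive", "constrictr_config_error")
  }
  if (!is.numeric(z_step_micron) || z_step_micron <= 0) {
    abort_constrictr("z_step_micron must be positive", "constrictr_config_error")
  }
  ranges <- lapply(masked_frame_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      abort_constrictr(
        "each masked frame range must be c(start, end) with start <= end",
        "constrictr_config_error"
      )
    }
    r
  })
  if (length(ranges) > 1) {
    starts <- vapply(ranges, `[`, 1L, 1)
    ranges <- ranges[order(starts)]
  }
  structure(
    list(
      movie = as.character(movie), region = region,
      microns_per_pixel = as.numeric(microns_per_pixel),
      z_step_micron = as.numeric(z_step_micron),
      ap_axis_angle_deg = as.numeric(ap_axis_angle_deg),
      bfp_threshold = if (is.null(bfp_threshold)) NULL else as.numeric(bfp_threshold),
      masked_frame_ranges = ranges,
      genotype_overrides = as.list(genotype_overrides)
    ),
    class = "embryo_config"
  )
}

#' Read an embryo configuration from a YAML file
#'
#' @param path YAML file with keys matching the arguments of
#'   [embryo_config()].
#' @return An `embryo_config` object.
#' @export
read_embryo_config <- function(path) {
  if (!file.exists(path)) {
    abort_constrictr(sprintf("config file not found: %s", path), "constrictr_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- c("movie", "region", "microns_per_pixel", "z_step_micron",
             "ap_axis_angle_deg", "bfp_threshold", "masked_frame_ranges",
             "genotype_overrides")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(embryo_config, raw[intersect(names(raw), known)])
}

#' Write an embryo configuration to YAML
#'
#' @param config An `embryo_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_embryo_config <- function(config, path) {
  stopifnot(inherits(config, "embryo_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.embryo_config <- function(x, ...) {
  cat(sprintf("<embryo_config> movie '%s' (%s)\n", x$movie, x$region))
  cat(sprintf("  %g um/px, z-step %g um, AP axis at %g deg\n",
              x$microns_per_pixel, x$z_step_micron, x$ap_axis_angle_deg))
  cat(sprintf("  BFP threshold: %s; masked ranges: %d; overrides: %d\n",
              if (is.null(x$bfp_threshold)) "automatic" else format(x$bfp_threshold),
              length(x$masked_frame_ranges), length(x$genotype_overrides)))
  invisible(x)
}
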