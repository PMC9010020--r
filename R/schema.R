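# Data dictionary for the four tracking tables.
#
# Column order is canonical: it mirrors the order in which the source data
# dictionary enumerates fields, and read/write round-trips preserve it.

cell_surfaces_cols <- c(
  region = "c", movie = "c", track_id_cells = "c", minute = "i",
  center_x_cells = "d", center_y_cells = "d", vx_coords_cells = "c",
  CRISPR = "c", control_neighbors = "i", crispant_neighbors = "i",
  apical_area_pixels = "d", apical_area_pixels_smoothed = "d",
  apical_area_micron_smoothed = "d", apical_area_standardized = "d",
  medial_actin = "d", medial_actin_smoothed = "d",
  medial_actin_standardized = "d",
  junctional_actin = "d", junctional_actin_smoothed = "d",
  junctional_actin_standardized = "d",
  medial_Ncadherin = "d", medial_Ncadherin_smoothed = "d",
  medial_Ncadherin_standardized = "d",
  junctional_Ncadherin = "d", junctional_Ncadherin_smoothed = "d",
  junctional_Ncadherin_standardized = "d",
  medial_memBFP = "d", medial_memBFP_smoothed = "d",
  junctional_memBFP = "d", junctional_memBFP_smoothed = "d"
)

cell_surface_stats_cols <- c(
  region = "c", movie = "c", track_id_cells = "c", CRISPR = "c",
  at_mosaic_interface = "l",
  start_area_micron = "d", end_area_micron = "d",
  delta_apical_area = "d", delta_medial_actin = "d",
  delta_junctional_actin = "d", delta_medial_Ncadherin = "d",
  delta_junctional_Ncadherin = "d"
)

junctions_cols <- c(
  region = "c", movie = "c", track_id_junctions = "c", CRISPR = "c",
  minute = "i",
  vx_1_x = "d", vx_1_y = "d", vx_2_x = "d", vx_2_y = "d",
  actin = "d", actin_smooth = "d", actin_standardized = "d",
  Ncadherin = "d", Ncadherin_smooth = "d", Ncadherin_standardized = "d",
  length_px = "d", length_micron = "d", delta_z_micron = "d",
  length_corrected = "d", length_smooth = "d", length_standardized = "d",
  orientation = "d"
)

junction_stats_cols <- c(
  region = "c", movie = "c", track_id_junctions = "c", CRISPR = "c",
  delta_length = "d", delta_actin = "d", delta_Ncadherin = "d",
  mean_orientation = "d"
)

table_schemas <- list(
  cell_surfaces = cell_surfaces_cols,
  junctions = junctions_cols,
  cell_surface_stats = cell_surface_stats_cols,
  junction_stats = junction_stats_cols
)

# columns that must be present for a table to be usable at all
mandatory_cols <- list(
  cell_surfaces = c("region", "movie", "track_id_cells", "minute"),
  junctions = c("region", "movie", "track_id_junctions", "minute"),
  cell_surface_stats = c("region", "movie", "track_id_cells"),
  junction_stats = c("region", "movie", "track_id_junctions")
)

# raw fluorescence columns, masked (set missing) over anomaly frame ranges
cell_fluor_cols <- c(
  "medial_actin", "junctional_actin",
  "medial_Ncadherin", "junctional_Ncadherin",
  "medial_memBFP", "junctional_memBFP"
)
junction_fluor_cols <- c("actin", "Ncadherin")

#' Encode a vertex matrix as an `X:Y#X:Y` string
#'
#' Cell outlines are stored in the tracking tables as a single text field
#' holding the ordered vertex list in `X:Y#X:Y` format (pixel coordinates,
#' x rightward, y downward, 0-based).
#'
#' @param vertices Numeric matrix with two columns (x, y), one row per vertex.
#' @return A length-1 character string.
#' @seealso [decode_vertices()]
#' @export
#' @examples
#' encode_vertices(rbind(c(0, 0), c(4, 0), c(4, 4)))
encode_vertices <- function(vertices) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  paste(
    sprintf("%.15g:%.15g", vertices[, 1], vertices[, 2]),
    collapse = "#"
  )
}

#' Decode an `X:Y#X:Y` vertex string
#'
#' @param string Character scalar in `X:Y#X:Y` format.
#' @return Numeric matrix with columns `x` and `y`.
#' @export
decode_vertices <- function(string) {
  if (is.na(string) || !nzchar(string)) {
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  parts <- strsplit(strsplit(string, "#", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    abort_constrictr(
      sprintf("malformed vertex token '%s'", paste(parts[[which(bad)[1]]], collapse = ":")),
      "constrictr_parse_error"
    )
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    abort_constrictr("non-numeric coordinate in vertex string", "constrictr_parse_error")
  }
  colnames(m) <- c("x", "y")
  m
}
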