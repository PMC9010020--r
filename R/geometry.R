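#' Polygon area by the shoelace formula
#'
#' @param vertices Numeric matrix with two columns (x, y) listing the
#'   polygon's vertices in order (either winding). At least 3 vertices; the
#'   polygon must be simple (non-self-intersecting).
#' @return Absolute enclosed area, in the square of the coordinate unit.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # 1
polygon_area <- function(vertices) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  n <- nrow(vertices)
  if (n < 3) {
    abort_constrictr("a polygon needs at least 3 vertices", "constrictr_geometry_error")
  }
  if (is_self_intersecting(vertices)) {
    abort_constrictr("self-intersecting polygon", "constrictr_geometry_error")
  }
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# segment-crossing test over non-adjacent edge pairs (O(n^2); polygons here
# are cell outlines with ~6 vertices)
is_self_intersecting <- function(v) {
  n <- nrow(v)
  if (n <= 3) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d2 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      d3 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d4 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Correct a projected junction length for z-displacement
#'
#' Time-lapse junction lengths measured on a maximum-intensity projection
#' underestimate the true length when the two vertices sit at different
#' depths. The correction restores the 3D chord length as the hypotenuse of
#' the projected length and the z-offset.
#'
#' @param length_micron Projected (in-plane) length, µm, non-negative.
#' @param delta_z_micron Absolute z-distance between the two vertices, µm,
#'   non-negative.
#' @return Corrected length `sqrt(length_micron^2 + delta_z_micron^2)`, µm.
#' @export
#' @examples
#' corrected_length(3, 4) # 5
corrected_length <- function(length_micron, delta_z_micron) {
  if (any(length_micron < 0, na.rm = TRUE) || any(delta_z_micron < 0, na.rm = TRUE)) {
    abort_constrictr("lengths and z-offsets must be non-negative",
                     "constrictr_geometry_error")
  }
  sqrt(length_micron^2 + delta_z_micron^2)
}

#' Junction orientation relative to the embryonic axes
#'
#' Returns the acute angle between a junction chord and the mediolateral
#' (ML) axis, in degrees folded to \[0, 90\]: 0° means aligned with the ML
#' axis, 90° aligned with the anteroposterior (AP) axis. The AP axis's
#' image-frame angle comes from the embryo config, so the result is
#' invariant to how the embryo was mounted; it is also invariant to
#' endpoint order.
#'
#' @param x1,y1,x2,y2 Segment endpoints in pixel image coordinates
#'   (x rightward, y downward). Vectorized.
#' @param config An [embryo_config()] (its `ap_axis_angle_deg` is used), or
#'   a number giving the AP-axis angle directly.
#' @return Orientation in degrees in \[0, 90\].
#' @export
junction_orientation <- function(x1, y1, x2, y2, config = 90) {
  ap <- if (inherits(config, "embryo_config")) config$ap_axis_angle_deg else as.numeric(config)
  dx <- x2 - x1; dy <- y2 - y1
  if (any(dx == 0 & dy == 0, na.rm = TRUE)) {
    abort_constrictr("zero-length segment has no orientation",
                     "constrictr_geometry_error")
  }
  theta <- atan2(dy, dx) * 180 / pi
  # acute angle to the AP axis, then convert so ML alignment reads 0
  to_ap <- abs(((theta - ap + 90) %% 180) - 90)
  90 - to_ap
}

#' Classify a junction as AP or ML by mean orientation
#'
#' Junctions whose mean orientation is below 45° join an anterior neighbor
#' to a posterior one (AP junctions); those at or above 45° are
#' mediolateral (ML). The 45° boundary itself classifies as ML.
#'
#' @param mean_orientation Numeric in \[0, 90\] (vectorized).
#' @return Character vector of `"AP"` / `"ML"`.
#' @export
#' @examples
#' classify_orientation(c(30, 60)) # "AP" "ML"
classify_orientation <- function(mean_orientation) {
  ok <- is.na(mean_orientation) |
    (mean_orientation >= 0 & mean_orientation <= 90)
  if (!all(ok)) {
    abort_constrictr("mean_orientation must lie in [0, 90]",
                     "constrictr_geometry_error")
  }
  ifelse(is.na(mean_orientation), NA_character_,
         ifelse(mean_orientation < 45, "AP", "ML"))
}
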