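#' Construct a label frame
#'
#' One segmented movie frame: an integer label image (0 = boundary
#' skeleton / background, k >= 1 = cell k) plus named channel intensity
#' images of the same shape, and optionally the z-index map recording which
#' z-slice the maximum-intensity projection sampled at each pixel.
#'
#' @param labels Integer matrix of cell labels.
#' @param channels Named list of numeric matrices, same dimension as
#'   `labels`.
#' @param z_index_map Optional integer matrix of projected z indices.
#' @return A `label_frame` object.
#' @export
label_frame <- function(labels, channels = list(), z_index_map = NULL) {
  stopifnot(is.matrix(labels))
  for (ch in channels) {
    if (!identical(dim(ch), dim(labels))) {
      abort_constrictr("channel dimensions must match the label image",
                       "constrictr_parameter_error")
    }
  }
  structure(list(labels = labels, channels = channels,
                 z_index_map = z_index_map),
            class = "label_frame")
}

# shift a matrix by (di, dj), padding with `fill`
shift_mat <- function(m, di, dj, fill = FALSE) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  si <- max(1, 1 - di):min(n, n - di)
  sj <- max(1, 1 - dj):min(p, p - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

neighbor_offsets_8 <- cbind(
  di = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dj = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# TRUE where any 8-neighbor of the pixel satisfies `mask`
dilate8 <- function(mask) {
  out <- mask
  for (k in seq_len(nrow(neighbor_offsets_8))) {
    out <- out | shift_mat(mask, neighbor_offsets_8[k, 1],
                           neighbor_offsets_8[k, 2])
  }
  out
}

# erosion by the 3x3 (8-connected) structuring element; pixels outside the
# image count as background, so cells touching the border erode there too
erode8 <- function(mask) {
  out <- mask
  for (k in seq_len(nrow(neighbor_offsets_8))) {
    out <- out & shift_mat(mask, neighbor_offsets_8[k, 1],
                           neighbor_offsets_8[k, 2])
  }
  out
}

#' Split a cell into medial and junctional domains
#'
#' The medial domain is the cell's pixel region after a one-pixel
#' constriction (erosion by the 3x3 structuring element); the junctional
#' domain is the set of boundary-skeleton pixels 8-adjacent to the cell
#' region. The two masks are disjoint by construction. Cells so small that
#' erosion empties them are flagged degenerate; their medial measurements
#' are reported missing downstream.
#'
#' @param frame A [label_frame()].
#' @param cell Cell label (integer >= 1) present in the frame.
#' @return List with logical matrices `medial` and `junctional`, and
#'   `degenerate` (TRUE when the medial mask is empty).
#' @export
split_domains <- function(frame, cell) {
  stopifnot(inherits(frame, "label_frame"))
  region <- frame$labels == cell
  if (!any(region)) {
    abort_constrictr(sprintf("cell %s not present in frame", cell),
                     "constrictr_parameter_error")
  }
  medial <- erode8(region)
  junctional <- (frame$labels == 0) & dilate8(region)
  list(medial = medial, junctional = junctional,
       degenerate = !any(medial))
}

#' Mean intensity over a pixel mask
#'
#' The domain intensity definition: total fluorescence of a region divided
#' by the area of the region, i.e. the arithmetic mean of the channel over
#' the mask pixels. An empty mask yields a missing value.
#'
#' @param mask Logical matrix.
#' @param channel Numeric matrix of the same dimension.
#' @return Mean intensity, or `NA` for an empty mask.
#' @export
mean_intensity <- function(mask, channel) {
  stopifnot(identical(dim(mask), dim(channel)))
  if (!any(mask)) return(NA_real_)
  mean(channel[mask])
}

#' Measure one cell's apical area and domain intensities
#'
#' The apical area is the pixel count of the medial mask (the area within a
#' one-pixel constriction of the segmented junctions); medial and
#' junctional mean intensities are computed per channel via
#' [mean_intensity()]. Degenerate cells (empty medial mask) report missing
#' medial values.
#'
#' @param frame A [label_frame()].
#' @param cell Cell label.
#' @return A one-row tibble: `cell`, `apical_area_pixels`, `degenerate`,
#'   and `medial_<channel>` / `junctional_<channel>` columns.
#' @export
measure_cell <- function(frame, cell) {
  dom <- split_domains(frame, cell)
  out <- tibble::tibble(cell = cell,
                        apical_area_pixels = sum(dom$medial),
                        degenerate = dom$degenerate)
  for (nm in names(frame$channels)) {
    ch <- frame$channels[[nm]]
    out[[paste0("medial_", nm)]] <-
      if (dom$degenerate) NA_real_ else mean_intensity(dom$medial, ch)
    out[[paste0("junctional_", nm)]] <- mean_intensity(dom$junctional, ch)
  }
  out
}

#' Measure every cell in a frame
#'
#' @param frame A [label_frame()].
#' @return Tibble with one row per nonzero label, as from [measure_cell()].
#' @export
measure_frame <- function(frame) {
  cells <- sort(setdiff(unique(as.vector(frame$labels)), 0))
  dplyr::bind_rows(lapply(cells, function(k) measure_cell(frame, k)))
}

# count of distinct nonzero labels among the 8-neighbors of each pixel
adjacent_label_count <- function(labels) {
  n_lab <- max(labels)
  counts <- matrix(0L, nrow(labels), ncol(labels))
  for (lab in seq_len(n_lab)) {
    if (!any(labels == lab)) next
    counts <- counts + dilate8(labels == lab)
  }
  counts
}

#' Junction pixels and z-displacement between two adjacent cells
#'
#' The junction between cells `cell_a` and `cell_b` is the set of skeleton
#' pixels 8-adjacent to both regions, excluding vertex pixels (skeleton
#' pixels adjacent to three or more cells). Mean junction intensity per
#' channel is computed over those pixels. When a z-stack is supplied, each
#' vertex's z is where the maximum-intensity projection sampled the stack
#' (argmax over z at the vertex pixel, ties resolving to the smallest z),
#' and `delta_z_micron` is the absolute z-difference between the two
#' vertices times the z-step.
#'
#' @param frame A [label_frame()].
#' @param cell_a,cell_b Adjacent cell labels.
#' @param z_stack Optional 3D array (rows x cols x z) of the intensity
#'   stack used for the projection.
#' @param z_step_micron z-spacing of the stack in µm (default 1).
#' @return List with `pixels` (logical matrix), `vertices` (logical
#'   matrix of the pair's vertex pixels), `mean_intensity` (named vector
#'   per channel) and `delta_z_micron` (`NA` without a stack or with fewer
#'   than two vertex pixels).
#' @export
junction_pixels <- function(frame, cell_a, cell_b, z_stack = NULL,
                            z_step_micron = 1) {
  stopifnot(inherits(frame, "label_frame"))
  skel <- frame$labels == 0
  near_a <- dilate8(frame$labels == cell_a)
  near_b <- dilate8(frame$labels == cell_b)
  shared <- skel & near_a & near_b
  if (!any(shared)) {
    abort_constrictr(sprintf("cells %s and %s are not adjacent", cell_a, cell_b),
                     "constrictr_adjacency_error")
  }
  n_adj <- adjacent_label_count(frame$labels)
  vertices <- shared & n_adj >= 3
  pixels <- shared & n_adj < 3
  means <- vapply(frame$channels, function(ch) mean_intensity(pixels, ch), 0)
  delta_z <- NA_real_
  if (!is.null(z_stack)) {
    vidx <- which(vertices, arr.ind = TRUE)
    if (nrow(vidx) >= 2) {
      # endpoints: the two vertex pixels farthest apart
      d2 <- as.matrix(stats::dist(vidx))
      far <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
      z_at <- function(ij) which.max(z_stack[ij[1], ij[2], ])
      delta_z <- abs(z_at(vidx[far[1], ]) - z_at(vidx[far[2], ])) *
        z_step_micron
    }
  }
  list(pixels = pixels, vertices = vertices, mean_intensity = means,
       delta_z_micron = delta_z)
}

#' Read a label frame from TIFF files
#'
#' @param label_path Single-frame TIFF of integer cell labels.
#' @param channel_paths Named character vector of channel TIFF paths.
#' @param label_scale Factor the labels were divided by when written
#'   (see [write_label_frame()]).
#' @return A [label_frame()].
#' @export
read_label_frame <- function(label_path, channel_paths = character(),
                             label_scale = 65535) {
  labels <- round(tiff::readTIFF(label_path) * label_scale)
  storage.mode(labels) <- "integer"
  channels <- lapply(channel_paths, function(p) tiff::readTIFF(p))
  label_frame(labels, channels)
}

#' Write a label frame to TIFF files
#'
#' Labels are written as 16-bit TIFF (scaled by `label_scale`); channels as
#' 32-bit float TIFF. Channel values must lie in \[0, 1\].
#'
#' @param frame A [label_frame()].
#' @param label_path Output path for the label image.
#' @param channel_paths Named character vector of output paths, one per
#'   channel in `frame$channels`.
#' @param label_scale Scaling divisor for the 16-bit label image.
#' @return Invisibly, all paths written.
#' @export
write_label_frame <- function(frame, label_path, channel_paths = character(),
                              label_scale = 65535) {
  stopifnot(inherits(frame, "label_frame"))
  tiff::writeTIFF(frame$labels / label_scale, label_path,
                  bits.per.sample = 16)
  for (nm in names(channel_paths)) {
    tiff::writeTIFF(frame$channels[[nm]], channel_paths[[nm]],
                    bits.per.sample = 32)
  }
  invisible(c(label_path, channel_paths))
}
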