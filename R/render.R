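# scanline fill of one polygon onto an integer label matrix (in place
# semantics via returned index vector). Pixel centers at integer coords.
polygon_pixel_rows <- function(xs, ys, n_row, n_col) {
  out <- integer(0)
  y_min <- max(1L, ceiling(min(ys)))
  y_max <- min(n_row, floor(max(ys)))
  if (y_min > y_max) return(out)
  n <- length(xs)
  nxt <- c(2:n, 1)
  for (yr in y_min:y_max) {
    # x-crossings of edges with the horizontal line y = yr
    cross <- numeric(0)
    for (m in seq_len(n)) {
      y1 <- ys[m]; y2 <- ys[nxt[m]]
      if ((y1 <= yr && y2 > yr) || (y2 <= yr && y1 > yr)) {
        x1 <- xs[m]; x2 <- xs[nxt[m]]
        cross <- c(cross, x1 + (yr - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    cross <- sort(cross)
    i <- 1
    while (i + 1 <= length(cross)) {
      xa <- max(1L, ceiling(cross[i]))
      xb <- min(n_col, floor(cross[i + 1]))
      if (xa <= xb) out <- c(out, (yr - 1L) * n_col + xa:xb)
      i <- i + 2
    }
  }
  out
}

#' Render one simulated frame as a label image with painted channels
#'
#' Rasterizes the frame's cell polygons onto a pixel grid with a 1-px
#' boundary skeleton (label 0) separating cells, then paints each cell's
#' medial domain uniformly with its tabulated intensity and each boundary
#' pixel with the mean of its flanking cells' junctional intensities. The
#' per-domain means actually painted are recorded (by direct pixel
#' enumeration) so measurement closure can be tested against them.
#'
#' @param sim Output of [simulate_epithelium()].
#' @param minute Frame to render.
#' @param channels Channel names to paint (default the four actin /
#'   N-cadherin channels plus medial membrane-BFP).
#' @return List with `frame` (a [label_frame()]), `painted` (tibble of
#'   per-cell painted medial/junctional means per channel), and
#'   `cell_labels` (map from label integer to cell track id).
#' @export
render_frames <- function(sim, minute = 1,
                          channels = c("medial_actin", "junctional_actin",
                                       "medial_Ncadherin",
                                       "junctional_Ncadherin",
                                       "medial_memBFP")) {
  pos <- sim$positions[minute, , ]
  idx <- do.call(rbind, sim$mesh$cells)
  n <- nrow(idx)
  n_col <- ceiling(max(pos[, 1]) + 2)
  n_row <- ceiling(max(pos[, 2]) + 2)
  if (n_row * n_col > 4e6) {
    abort_constrictr("raster too large; reduce cell count or size",
                     "constrictr_config_error")
  }
  # fill cells; matrix is indexed [row = y, col = x] but we build by linear
  # index over an x-fast layout and transpose-free bookkeeping via (y,x)
  labels <- matrix(0L, n_row, n_col)
  for (ci in seq_len(n)) {
    xs <- pos[idx[ci, ], 1]; ys <- pos[idx[ci, ], 2]
    lin <- polygon_pixel_rows(xs, ys, n_row, n_col)
    if (length(lin) == 0) next
    yr <- (lin - 1L) %/% n_col + 1L
    xc <- (lin - 1L) %% n_col + 1L
    labels[cbind(yr, xc)] <- ci
  }
  # carve the 1-px skeleton: zero any pixel whose right or lower 4-neighbor
  # holds a different nonzero label (leaves no two labels 4-adjacent)
  right_diff <- labels[, -1] != labels[, -n_col] &
    labels[, -1] > 0 & labels[, -n_col] > 0
  down_diff <- labels[-1, ] != labels[-n_row, ] &
    labels[-1, ] > 0 & labels[-n_row, ] > 0
  zero <- matrix(FALSE, n_row, n_col)
  zero[, -n_col][right_diff] <- TRUE
  zero[-1, ][down_diff] <- TRUE
  labels[zero] <- 0L

  # channel painting
  tab <- sim$truth$channel_means
  chan_imgs <- list()
  region <- lapply(seq_len(n), function(ci) labels == ci)
  # junctional value per cell at this frame
  jn_col <- function(nm) sub("^medial_", "junctional_", nm)
  for (nm in channels) {
    img <- matrix(0, n_row, n_col)
    med_val <- tab[[nm]][, minute]
    for (ci in seq_len(n)) img[region[[ci]]] <- med_val[ci]
    chan_imgs[[nm]] <- img
  }
  # paint skeleton pixels with the mean junctional value of flanking cells
  skel <- which(labels == 0, arr.ind = TRUE)
  flank <- flanking_cells(labels, skel)
  for (nm in channels) {
    base_nm <- if (startsWith(nm, "junctional_")) nm else jn_col(nm)
    jn_val <- tab[[base_nm]][, minute]
    img <- chan_imgs[[nm]]
    for (k in seq_len(nrow(skel))) {
      cells_here <- flank[[k]]
      if (length(cells_here) > 0) {
        img[skel[k, 1], skel[k, 2]] <- mean(jn_val[cells_here])
      }
    }
    chan_imgs[[nm]] <- img
  }
  frame <- label_frame(labels, chan_imgs)

  # record painted per-domain means by direct pixel enumeration
  painted <- vector("list", n)
  for (ci in seq_len(n)) {
    med_mask <- enum_erode(labels, ci)
    jn_mask <- enum_adjacent_skeleton(labels, ci)
    row <- tibble::tibble(cell = ci,
                          track_id_cells = sim$mesh$cell_ids[ci])
    for (nm in channels) {
      img <- chan_imgs[[nm]]
      row[[paste0("painted_medial_", nm)]] <-
        if (any(med_mask)) mean(img[med_mask]) else NA_real_
      row[[paste0("painted_junctional_", nm)]] <-
        if (any(jn_mask)) mean(img[jn_mask]) else NA_real_
    }
    painted[[ci]] <- row
  }
  list(frame = frame, painted = dplyr::bind_rows(painted),
       cell_labels = setNames(sim$mesh$cell_ids, seq_len(n)))
}

# flanking nonzero labels of each skeleton pixel (8-neighborhood), by
# explicit neighborhood scan
flanking_cells <- function(labels, skel) {
  n_row <- nrow(labels); n_col <- ncol(labels)
  lapply(seq_len(nrow(skel)), function(k) {
    r <- skel[k, 1]; c <- skel[k, 2]
    rr <- max(1, r - 1):min(n_row, r + 1)
    cc <- max(1, c - 1):min(n_col, c + 1)
    setdiff(unique(as.vector(labels[rr, cc])), 0L)
  })
}

# pixel-loop erosion used only for recording painted ground truth, kept
# independent of the measurement module's vectorized erode8
enum_erode <- function(labels, cell) {
  n_row <- nrow(labels); n_col <- ncol(labels)
  out <- matrix(FALSE, n_row, n_col)
  hits <- which(labels == cell, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    r <- hits[k, 1]; c <- hits[k, 2]
    if (r == 1 || c == 1 || r == n_row || c == n_col) next
    if (all(labels[(r - 1):(r + 1), (c - 1):(c + 1)] == cell)) {
      out[r, c] <- TRUE
    }
  }
  out
}

enum_adjacent_skeleton <- function(labels, cell) {
  n_row <- nrow(labels); n_col <- ncol(labels)
  out <- matrix(FALSE, n_row, n_col)
  hits <- which(labels == 0L, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    r <- hits[k, 1]; c <- hits[k, 2]
    rr <- max(1, r - 1):min(n_row, r + 1)
    cc <- max(1, c - 1):min(n_col, c + 1)
    if (any(labels[rr, cc] == cell)) out[r, c] <- TRUE
  }
  out
}
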