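# Shared fixtures, built in code at test time.

# a tiny hand-written 3-cell dataset covering the cell table schema
tiny_cell_dataset <- function() {
  cells <- dplyr::bind_rows(lapply(1:3, function(k) {
    minutes <- 1:5
    area <- 100 - k * minutes
    tibble::tibble(
      region = "anterior", movie = "emb1",
      track_id_cells = sprintf("c%03d", k), minute = minutes,
      center_x_cells = 10 * k + 0.25, center_y_cells = 20 + 0.5 * minutes,
      vx_coords_cells = encode_vertices(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)) + k),
      CRISPR = if (k == 3) "shroom3 crispant" else "control",
      control_neighbors = 2L, crispant_neighbors = if (k == 2) 1L else 0L,
      apical_area_pixels = area,
      medial_actin = 50 + k + sin(minutes),
      junctional_actin = 60 + k + cos(minutes),
      medial_Ncadherin = 30 + k + minutes / 7,
      junctional_Ncadherin = 40 + k - minutes / 9,
      medial_memBFP = if (k == 3) 1000 else 100,
      junctional_memBFP = if (k == 3) 1200 else 120
    )
  }))
  tracking_dataset(cell_surfaces = cells)
}

default_embryo_config <- function(...) {
  embryo_config(movie = "sim_a", region = "anterior",
                microns_per_pixel = 0.5, z_step_micron = 1,
                ap_axis_angle_deg = 90, ...)
}

# small simulated cohort reused across tests (computed once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_cells = 60, n_frames = 40, seed = 42,
                              crispant_fraction = 0.3)
      cache <<- simulate_epithelium(cfg)
    }
    cache
  }
})

# a toy 3-cell label frame with explicit geometry:
# two 5x5 cells side by side separated by a 1-px skeleton column, and a
# third cell below, separated by a skeleton row
toy_three_cell_frame <- function() {
  labels <- matrix(0L, 13, 13)
  labels[2:6, 2:6] <- 1L
  labels[2:6, 8:12] <- 2L
  labels[8:12, 2:12] <- 3L
  channels <- list(
    actin = matrix(as.numeric(seq_len(13 * 13)), 13, 13),
    flat = matrix(7, 13, 13)
  )
  label_frame(labels, channels)
}
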