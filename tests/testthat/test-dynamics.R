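test_that("delta statistic is last minus first usable value", {
  expect_identical(delta_stat(rep(0.4, 6)), 0)
  expect_identical(delta_stat(c(-1.2, 0, 0.5, 0.8)), 2)
  expect_true(is.na(delta_stat(c(NA, 3, NA))))
  set.seed(41)
  for (rep in 1:20) {
    v <- rnorm(25)
    v[sample(25, 4)] <- NA
    usable <- v[!is.na(v)]
    expect_identical(delta_stat(v), usable[length(usable)] - usable[1])
    # antisymmetric under time reversal
    expect_identical(delta_stat(rev(v)), -delta_stat(v))
  }
})

test_that("track summaries reproduce a per-track oracle recomputation", {
  sim <- small_sim()
  ds <- preprocess_tables(sim$dataset, default_embryo_config(), quiet = TRUE)
  ds <- summarize_tracks(ds)
  stats <- ds$cell_surface_stats
  expect_identical(nrow(stats),
                   dplyr::n_distinct(ds$cell_surfaces$track_id_cells))
  one <- stats$track_id_cells[5]
  track <- ds$cell_surfaces[ds$cell_surfaces$track_id_cells == one, ]
  track <- track[order(track$minute), ]
  z <- track$apical_area_standardized
  expect_equal(stats$delta_apical_area[stats$track_id_cells == one],
               z[length(z)] - z[1], tolerance = 1e-12)
  a <- track$apical_area_micron_smoothed
  expect_equal(stats$start_area_micron[stats$track_id_cells == one], a[1],
               tolerance = 1e-12)
  expect_equal(stats$end_area_micron[stats$track_id_cells == one],
               a[length(a)], tolerance = 1e-12)
  # junction summary: a fixed-orientation junction keeps its orientation
  jstats <- ds$junction_stats
  jone <- jstats$track_id_junctions[1]
  jtrack <- ds$junctions[ds$junctions$track_id_junctions == jone, ]
  expect_equal(jstats$mean_orientation[jstats$track_id_junctions == jone],
               mean(jtrack$orientation), tolerance = 1e-12)
  expect_true(all(jstats$mean_orientation >= 0 & jstats$mean_orientation <= 90))
})

test_that("summarizing a single-track dataset yields one row", {
  cs <- tibble::tibble(
    region = "anterior", movie = "m", track_id_cells = "c1", minute = 1:10,
    apical_area_micron_smoothed = 100 - (1:10),
    apical_area_standardized = as.numeric(scale(100 - (1:10)))
  )
  out <- summarize_tracks(tracking_dataset(cell_surfaces = cs))
  expect_identical(nrow(out$cell_surface_stats), 1L)
  expect_lt(out$cell_surface_stats$delta_apical_area, 0)
})

test_that("quadrant fractions count points into four percentages", {
  q <- quadrant_fractions(c(-1, -2, -3), c(-1, -0.5, -2))
  expect_identical(unname(q), c(100, 0, 0, 0))
  q4 <- quadrant_fractions(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_identical(unname(q4), c(25, 25, 25, 25))
  set.seed(42)
  x <- rnorm(1000); y <- rnorm(1000)
  q <- quadrant_fractions(x, y)
  # counting oracle
  expect_identical(unname(q[1]), 100 * sum(x < 0 & y < 0) / 1000)
  expect_identical(unname(q[4]), 100 * sum(x >= 0 & y >= 0) / 1000)
  expect_lt(abs(sum(q) - 100), 0.01)
  # zero deltas land in the non-negative quadrants
  expect_identical(unname(quadrant_fractions(0, 0)), c(0, 0, 0, 100))
  expect_error(quadrant_fractions(numeric(), numeric()),
               class = "constrictr_parameter_error")
})

# hand-built adjacency series: hexagonal quad A,B losing contact, C,D gaining
scripted_adjacency <- function(n_frames, swap_at = NULL, flicker = NULL) {
  base <- tibble::tibble(
    cell_a = c("A", "A", "A", "B", "B", "C", "D"),
    cell_b = c("B", "C", "D", "C", "D", "E", "E")
  )
  rows <- lapply(seq_len(n_frames), function(t) {
    adj <- base
    if (!is.null(swap_at) && t >= swap_at) {
      adj <- adj[!(adj$cell_a == "A" & adj$cell_b == "B"), ]
      adj <- dplyr::bind_rows(adj, tibble::tibble(cell_a = "C", cell_b = "D"))
    }
    if (!is.null(flicker) && t %in% flicker) {
      adj <- adj[!(adj$cell_a == "A" & adj$cell_b == "B"), ]
    }
    adj$minute <- t
    adj
  })
  dplyr::bind_rows(rows)
}

test_that("a scripted exchange persisting to the end is one stable event", {
  adj <- scripted_adjacency(20, swap_at = 10)
  res <- detect_t1(adj)
  expect_identical(nrow(res$events), 1L)
  expect_setequal(unname(unlist(res$events[1, c("cell_a", "cell_b")])),
                  c("A", "B"))
  expect_setequal(unname(unlist(res$events[1, c("cell_c", "cell_d")])),
                  c("C", "D"))
  expect_identical(res$events$loss_frame, 10L)
  counted <- res$counts$t1_count[res$counts$track_id_cells %in% c("A", "B", "C", "D")]
  expect_identical(counted, rep(1L, 4))
  expect_identical(sum(res$counts$t1_count), 4L)
})

test_that("short flicker and static meshes yield no events", {
  expect_identical(nrow(detect_t1(scripted_adjacency(20))$events), 0L)
  flick <- scripted_adjacency(20, flicker = c(8, 9))
  expect_identical(nrow(detect_t1(flick)$events), 0L)
})

test_that("per-cell counts always sum to four times the event count", {
  for (E in c(0L, 1L)) {
    adj <- scripted_adjacency(25, swap_at = if (E > 0) 12 else NULL)
    res <- detect_t1(adj)
    expect_identical(nrow(res$events), E)
    expect_identical(sum(res$counts$t1_count), 4L * E)
  }
})

test_that("generator-scripted exchanges are recovered exactly", {
  for (E in c(0L, 1L, 3L)) {
    cfg <- synthetic_config(n_cells = 64, n_frames = 40, seed = 43 + E,
                            t1_frames = if (E > 0) seq(12, by = 8, length.out = E)
                            else integer())
    sim <- simulate_epithelium(cfg)
    res <- detect_t1(sim$adjacency)
    expect_identical(nrow(res$events), E)
    expect_identical(sum(res$counts$t1_count), 4L * E)
    if (E > 0) {
      got <- res$events[order(res$events$loss_frame), ]
      truth <- sim$truth$t1_events[order(sim$truth$t1_events$frame), ]
      expect_identical(as.integer(got$loss_frame), as.integer(truth$frame))
      for (i in seq_len(E)) {
        expect_setequal(unname(unlist(got[i, c("cell_a", "cell_b")])),
                        unname(unlist(truth[i, c("cell_a", "cell_b")])))
        expect_setequal(unname(unlist(got[i, c("cell_c", "cell_d")])),
                        unname(unlist(truth[i, c("cell_c", "cell_d")])))
      }
    }
  }
})
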