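make_track <- function(id, n, movie = "m1", region = "anterior") {
  tibble::tibble(
    region = region, movie = movie, track_id_cells = id, minute = seq_len(n),
    apical_area_pixels = 100 + seq_len(n), medial_actin = 50 + seq_len(n)
  )
}

test_that("track filters keep 30/15-frame tracks and drop shorter ones", {
  cs <- dplyr::bind_rows(make_track("keep", 30), make_track("drop", 29))
  jx <- tibble::tibble(
    region = "anterior", movie = "m1",
    track_id_junctions = rep(c("jkeep", "jdrop"), c(15, 14)),
    minute = c(1:15, 1:14), actin = 1
  )
  ds <- filter_tracks(tracking_dataset(cell_surfaces = cs, junctions = jx),
                      quiet = TRUE)
  expect_setequal(unique(ds$cell_surfaces$track_id_cells), "keep")
  expect_setequal(unique(ds$junctions$track_id_junctions), "jkeep")
  expect_identical(unname(attr(ds, "filter_log")),
                   c(1L, 1L))
  # empty dataset passes through
  empty <- filter_tracks(tracking_dataset(cell_surfaces = cs[0, ]), quiet = TRUE)
  expect_identical(nrow(empty$cell_surfaces), 0L)
})

test_that("7-frame smoothing truncates at ends and skips masked frames", {
  expect_identical(smooth_series(rep(3, 10)), rep(3, 10))
  ramp <- as.numeric(0:9)
  sm <- smooth_series(ramp)
  # interior frames of a ramp keep their own value (symmetric window)
  expect_equal(sm[4:7], ramp[4:7])
  # first frame averages frames 1..4 (values 0..3)
  expect_identical(sm[1], 1.5)
  expect_error(smooth_series(ramp, window = 6),
               class = "constrictr_parameter_error")
  # masked frames contribute nothing and remain masked
  v <- c(1, 2, NA, 4, 5, 6, 7, 8)
  sm2 <- smooth_series(v)
  expect_true(is.na(sm2[3]))
  expect_identical(sm2[1], mean(c(1, 2, 4)))
  expect_identical(sm2[5], mean(c(2, 4, 5, 6, 7, 8)))
})

test_that("smoothing is shift-equivariant", {
  set.seed(9)
  v <- rnorm(30)
  expect_equal(smooth_series(v + 5), smooth_series(v) + 5, tolerance = 1e-12)
})

test_that("standardization gives mean 0 sd 1 and flags degenerate tracks", {
  z <- standardize_series(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # matches R's scale() convention (sample sd)
  set.seed(10)
  v <- rnorm(50)
  expect_equal(as.numeric(standardize_series(v)), as.numeric(scale(v)),
               tolerance = 1e-12)
  expect_lt(abs(mean(standardize_series(v))), 1e-9)
  expect_lt(abs(sd(standardize_series(v)) - 1), 1e-9)
  const <- standardize_series(rep(2, 5))
  expect_true(attr(const, "degenerate"))
  expect_true(all(is.na(const)))
  short <- standardize_series(c(NA, 4, NA))
  expect_true(attr(short, "degenerate"))
})

test_that("standardization is idempotent up to tolerance", {
  set.seed(11)
  v <- rnorm(40, mean = 7, sd = 3)
  once <- as.numeric(standardize_series(v))
  twice <- as.numeric(standardize_series(once))
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("anomaly masking removes fluorescence but keeps geometry", {
  cs <- make_track("a", 50)
  cs$medial_memBFP <- 100
  ds <- tracking_dataset(cell_surfaces = cs)
  cfg <- embryo_config("m1", "anterior", masked_frame_ranges = list(c(23, 45)))
  masked <- mask_frames(ds, cfg)
  hit <- masked$cell_surfaces$minute >= 23 & masked$cell_surfaces$minute <= 45
  expect_true(all(is.na(masked$cell_surfaces$medial_actin[hit])))
  expect_true(all(is.na(masked$cell_surfaces$medial_memBFP[hit])))
  expect_false(anyNA(masked$cell_surfaces$medial_actin[!hit]))
  # geometry is retained and the track is not split
  expect_false(anyNA(masked$cell_surfaces$apical_area_pixels))
  expect_identical(nrow(masked$cell_surfaces), 50L)
  # empty mask list leaves the dataset unchanged
  cfg0 <- embryo_config("m1", "anterior")
  expect_identical(mask_frames(ds, cfg0)$cell_surfaces, cs)
})

test_that("masked frames are excluded from smoothing windows", {
  cs <- make_track("a", 50)
  cfg <- embryo_config("m1", "anterior", masked_frame_ranges = list(c(23, 45)))
  out <- preprocess_tables(tracking_dataset(cell_surfaces = cs), cfg,
                           min_cell_frames = 30, quiet = TRUE)$cell_surfaces
  raw <- cs$medial_actin
  raw[23:45] <- NA
  # oracle: window mean over the remaining frames
  oracle <- vapply(seq_len(50), function(i) {
    w <- raw[max(1, i - 3):min(50, i + 3)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, 0)
  oracle[23:45] <- NA
  expect_equal(out$medial_actin_smoothed, oracle, tolerance = 1e-12)
})

test_that("pixel-to-micron conversion scales lengths and areas", {
  expect_identical(to_microns(100, "area", 0.5), 25)
  expect_identical(to_microns(10, "length", 0.5), 5)
  expect_identical(to_microns(3.7, "length", 1), 3.7)
  cfg <- default_embryo_config()
  expect_identical(to_microns(100, "area", cfg), 25)
  expect_error(to_microns(1, "length", 0), class = "constrictr_config_error")
})

test_that("the full preprocessing pipeline fills the derived columns", {
  sim <- small_sim()
  ds <- preprocess_tables(sim$dataset, default_embryo_config(), quiet = TRUE)
  cs <- ds$cell_surfaces
  expect_true(all(c("apical_area_pixels_smoothed", "apical_area_micron_smoothed",
                    "apical_area_standardized", "medial_actin_standardized",
                    "medial_memBFP_smoothed") %in% names(cs)))
  expect_equal(cs$apical_area_micron_smoothed,
               cs$apical_area_pixels_smoothed * 0.25, tolerance = 1e-12)
  jx <- ds$junctions
  expect_true(all(c("length_smooth", "length_standardized",
                    "actin_standardized") %in% names(jx)))
  expect_true(all(jx$length_corrected >= jx$length_micron - 1e-12))
  # derived tables still validate cleanly
  expect_identical(nrow(validate_tables(ds)), 0L)
})
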