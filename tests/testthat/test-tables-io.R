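test_that("write then read is the identity on a small dataset", {
  ds <- tiny_cell_dataset()
  dir <- withr::local_tempdir()
  write_tracking_tables(ds, dir)
  back <- read_tracking_tables(dir)
  expect_equal(back$cell_surfaces, ds$cell_surfaces, tolerance = 1e-9,
               ignore_attr = TRUE)
  # second write is byte-identical (fixed-point serialization)
  dir2 <- withr::local_tempdir()
  write_tracking_tables(back, dir2)
  expect_identical(readLines(file.path(dir, "cell_surfaces.csv")),
                   readLines(file.path(dir2, "cell_surfaces.csv")))
})

test_that("a file lacking a mandatory column raises a schema error naming it", {
  ds <- tiny_cell_dataset()
  ds$cell_surfaces$track_id_cells <- NULL
  dir <- withr::local_tempdir()
  write_tracking_tables(ds, dir)
  expect_error(read_tracking_tables(dir), "track_id_cells",
               class = "constrictr_schema_error")
})

test_that("a dictionary-exact header reads with no warnings or missing columns", {
  dir <- withr::local_tempdir()
  cols <- constrictr:::cell_surfaces_cols
  row <- c("anterior", "m1", "c001", "1", "1.5", "2.5", "0:0#1:0#1:1",
           "control", "1", "0", rep("3.25", length(cols) - 10))
  writeLines(c(paste(names(cols), collapse = ","),
               paste(row, collapse = ",")),
             file.path(dir, "cell_surfaces.csv"))
  expect_no_warning(ds <- read_tracking_tables(dir))
  expect_length(attr(ds$cell_surfaces, "missing_columns"), 0)
  expect_identical(names(ds$cell_surfaces), names(cols))
})

test_that("missing values serialize as empty cells, never zero", {
  ds <- tiny_cell_dataset()
  ds$cell_surfaces$medial_actin[2] <- NA_real_
  dir <- withr::local_tempdir()
  write_tracking_tables(ds, dir)
  lines <- readLines(file.path(dir, "cell_surfaces.csv"))
  fields <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  i <- which(strsplit(lines[1], ",")[[1]] == "medial_actin")
  expect_identical(fields[i], "")
  back <- read_tracking_tables(dir)
  expect_true(is.na(back$cell_surfaces$medial_actin[2]))
})

test_that("unknown extra columns are preserved with a warning", {
  ds <- tiny_cell_dataset()
  ds$cell_surfaces$custom_score <- seq_len(nrow(ds$cell_surfaces))
  dir <- withr::local_tempdir()
  write_tracking_tables(ds, dir)
  expect_warning(back <- read_tracking_tables(dir), "custom_score")
  expect_equal(back$cell_surfaces$custom_score,
               as.numeric(ds$cell_surfaces$custom_score))
})

test_that("an empty dataset writes header-only files", {
  ds <- tiny_cell_dataset()
  ds$cell_surfaces <- ds$cell_surfaces[0, ]
  dir <- withr::local_tempdir()
  write_tracking_tables(ds, dir)
  lines <- readLines(file.path(dir, "cell_surfaces.csv"))
  expect_length(lines, 1)
  expect_match(lines[1], "^region,movie,track_id_cells")
})

test_that("validate flags each schema invariant with row coordinates", {
  jx <- tibble::tibble(
    region = "posterior", movie = "m1", track_id_junctions = "j1",
    CRISPR = "control", minute = 1:3,
    vx_1_x = 0, vx_1_y = 0, vx_2_x = 1, vx_2_y = 1,
    actin = 1, Ncadherin = 1, length_px = 2, length_micron = 1,
    delta_z_micron = c(0, -1, 0), length_corrected = c(1.5, 1.5, 0.5),
    orientation = c(45, 95, 30)
  )
  report <- validate_tables(tracking_dataset(junctions = jx))
  expect_true(any(report$rule == "orientation in [0, 90]" & report$row == 2))
  expect_true(any(report$rule == "delta_z_micron >= 0" & report$row == 2))
  expect_true(any(report$rule == "length_corrected >= length_micron" &
                    report$row == 3))
})

test_that("validate flags standardized series that are not mean-0 sd-1", {
  cs <- tibble::tibble(
    region = "anterior", movie = "m1", track_id_cells = "c1", minute = 1:4,
    apical_area_pixels = c(4, 3, 2, 1),
    apical_area_standardized = c(0.5, 0.4, 0.6, 0.5)  # mean 0.5, not 0
  )
  report <- validate_tables(tracking_dataset(cell_surfaces = cs))
  expect_true(any(grepl("mean 0 and s.d. 1", report$rule)))
  # and a correctly standardized series passes
  cs$apical_area_standardized <-
    as.numeric(scale(cs$apical_area_pixels))
  expect_identical(nrow(validate_tables(tracking_dataset(cell_surfaces = cs))), 0L)
})

test_that("clean generator output yields an empty validation report", {
  sim <- small_sim()
  expect_identical(nrow(validate_tables(sim$dataset)), 0L)
})

test_that("vertex strings round-trip through the X:Y#X:Y encoding", {
  v <- matrix(c(0.123456789, 4.5, 10, 0.25, 7.75, 3), ncol = 2, byrow = TRUE)
  expect_equal(unname(decode_vertices(encode_vertices(v))), v,
               tolerance = 1e-12)
  expect_error(decode_vertices("1:2#3"), class = "constrictr_parse_error")
})

test_that("embryo config round-trips through YAML", {
  cfg <- embryo_config("emb_b", "posterior", 0.42, 1.5, 87,
                       bfp_threshold = 350,
                       masked_frame_ranges = list(c(23, 45)),
                       genotype_overrides = list(c007 = "control"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_embryo_config(cfg, path)
  back <- read_embryo_config(path)
  expect_equal(back, cfg)
  expect_error(embryo_config("x", "anterior", microns_per_pixel = -1),
               class = "constrictr_config_error")
  expect_error(embryo_config("x", "anterior",
                             masked_frame_ranges = list(c(10, 5))),
               class = "constrictr_config_error")
})
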