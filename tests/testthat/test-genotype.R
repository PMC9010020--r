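test_that("bimodal BFP scores are split to match generator truth", {
  cfg <- synthetic_config(n_cells = 220, n_frames = 12, seed = 31,
                          crispant_fraction = 0.4)
  sim <- simulate_epithelium(cfg)
  calls <- call_genotype(sim$dataset$cell_surfaces, default_embryo_config())
  truth <- sim$truth$genotype[calls$track_id_cells]
  expect_gte(mean(calls$CRISPR == truth), 0.99)
  expect_false(attr(calls, "degenerate"))
})

test_that("manual thresholds and overrides take precedence", {
  ds <- tiny_cell_dataset()
  ds$cell_surfaces$movie <- "sim_a"
  cfg <- default_embryo_config(bfp_threshold = 500)
  calls <- call_genotype(ds$cell_surfaces, cfg)
  expect_identical(calls$CRISPR[calls$track_id_cells == "c003"],
                   "shroom3 crispant")
  expect_identical(sum(calls$CRISPR == "control"), 2L)
  # all scores under the threshold -> all control
  cfg_hi <- default_embryo_config(bfp_threshold = 1e6)
  expect_true(all(call_genotype(ds$cell_surfaces, cfg_hi)$CRISPR == "control"))
  # an override wins regardless of score
  cfg_ov <- default_embryo_config(
    bfp_threshold = 500,
    genotype_overrides = list(c003 = "control")
  )
  calls_ov <- call_genotype(ds$cell_surfaces, cfg_ov)
  expect_identical(calls_ov$CRISPR[calls_ov$track_id_cells == "c003"], "control")
  expect_identical(calls_ov$source[calls_ov$track_id_cells == "c003"], "override")
})

test_that("a unimodal score distribution falls back to all-control", {
  set.seed(33)
  cs <- tibble::tibble(
    region = "anterior", movie = "sim_a",
    track_id_cells = sprintf("c%03d", rep(1:50, each = 3)),
    minute = rep(1:3, 50),
    medial_memBFP = rnorm(150, 200, 20)
  )
  expect_warning(calls <- call_genotype(cs, default_embryo_config()),
                 "bimodal")
  expect_true(all(calls$CRISPR == "control"))
  expect_true(attr(calls, "degenerate"))
})

test_that("the automatic threshold recovers a 5-sd mode separation", {
  set.seed(34)
  n <- 250
  truth <- rep(c("control", "shroom3 crispant"), c(150, 100))
  score <- ifelse(truth == "control", rnorm(n, 100, 50), rnorm(n, 1000, 50))
  cs <- tibble::tibble(
    region = "anterior", movie = "sim_a",
    track_id_cells = sprintf("c%03d", 1:n), minute = 1,
    medial_memBFP = pmax(score, 1)
  )
  calls <- call_genotype(cs, default_embryo_config())
  expect_lt(mean(calls$CRISPR != truth), 0.01)
})

test_that("neighbor counts partition each cell's neighborhood", {
  # hexagonal patch: center c0 surrounded by n1..n6 in a ring
  ring <- sprintf("n%d", 1:6)
  pairs <- dplyr::bind_rows(
    tibble::tibble(minute = 1, cell_a = "c0", cell_b = ring),
    tibble::tibble(minute = 1, cell_a = ring,
                   cell_b = ring[c(2:6, 1)])
  )
  labels <- c(c0 = "control", setNames(rep(c("control", "shroom3 crispant"), 3),
                                       ring))
  counts <- neighbor_counts(pairs, labels)
  c0 <- counts[counts$track_id_cells == "c0", ]
  expect_identical(c0$control_neighbors, 3L)
  expect_identical(c0$crispant_neighbors, 3L)
  # partition: counts sum to the degree for every cell
  deg <- table(c(pairs$cell_a, pairs$cell_b))
  for (i in seq_len(nrow(counts))) {
    expect_identical(counts$control_neighbors[i] + counts$crispant_neighbors[i],
                     as.integer(deg[[counts$track_id_cells[i]]]))
  }
  # an isolated cell reports (0, 0) via the roster
  roster <- tibble::tibble(minute = 1, track_id_cells = c("c0", ring, "lonely"))
  counts2 <- neighbor_counts(pairs, c(labels, lonely = "control"), cells = roster)
  lonely <- counts2[counts2$track_id_cells == "lonely", ]
  expect_identical(lonely$control_neighbors, 0L)
  expect_identical(lonely$crispant_neighbors, 0L)
  # unlabeled neighbor errors with the cell named
  expect_error(neighbor_counts(pairs, labels[-2]), "n1",
               class = "constrictr_label_error")
})

test_that("interface flags fire on any-frame opposite contact", {
  counts <- tibble::tibble(
    minute = rep(1:3, 3),
    track_id_cells = rep(c("a", "b", "c"), each = 3),
    control_neighbors = c(2, 2, 2, 0, 0, 0, 0, 0, 0),
    crispant_neighbors = c(0, 1, 0, 0, 0, 0, 0, 0, 0)
  )
  labels <- c(a = "control", b = "control", c = "shroom3 crispant")
  flags <- flag_interface(counts, labels)
  expect_true(flags$at_mosaic_interface[flags$track_id_cells == "a"])
  expect_false(flags$at_mosaic_interface[flags$track_id_cells == "b"])
  # a crispant with zero neighbors ever is not at the interface
  expect_false(flags$at_mosaic_interface[flags$track_id_cells == "c"])
})

test_that("junction status follows the flanking genotypes symmetrically", {
  expect_identical(classify_junction("control", "control"), "control")
  expect_identical(classify_junction("shroom3 crispant", "shroom3 crispant"),
                   "shroom3 crispant")
  expect_identical(classify_junction("control", "shroom3 crispant"),
                   "at mosaic interface")
  expect_identical(classify_junction("shroom3 crispant", "control"),
                   "at mosaic interface")
  expect_error(classify_junction("control", "mutant"),
               class = "constrictr_label_error")
})

test_that("excluding interface cells and junctions removes all mixed flanks", {
  sim <- small_sim()
  calls <- call_genotype(sim$dataset$cell_surfaces, default_embryo_config())
  labels <- setNames(calls$CRISPR, calls$track_id_cells)
  counts <- neighbor_counts(sim$adjacency, labels)
  flags <- flag_interface(counts, labels)
  kept <- flags$track_id_cells[!flags$at_mosaic_interface]
  # exhaustive scan: no kept cell ever borders the opposite genotype
  adj <- sim$adjacency
  opp <- labels[adj$cell_a] != labels[adj$cell_b]
  expect_false(any(adj$cell_a[opp] %in% kept | adj$cell_b[opp] %in% kept))
  # junction exclusion mirrors the cell rule
  status <- classify_junction(unname(labels[adj$cell_a]),
                              unname(labels[adj$cell_b]))
  expect_identical(status == "at mosaic interface", unname(opp))
})
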