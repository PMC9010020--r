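#' End-to-end pipeline driver
#'
#' Runs the pipeline stages over a synthetic configuration, writing every
#' stage's outputs and a JSON run manifest under `out_dir`:
#'
#' * `simulate` — generate the tracked epithelium, write raw
#'   `cell_surfaces.csv` / `junctions.csv`, the per-frame `adjacency.csv`
#'   and the ground-truth genotype/regime table (`ground_truth.csv`,
#'   synthetic labels kept for recovery checks only).
#' * `preprocess` — masking, track filtering, smoothing, unit conversion,
#'   standardization; rewrites the tables with derived columns.
#' * `analyze` — genotype calling from membrane-BFP, neighbor counts,
#'   interface flags, junction status, per-track summaries
#'   (`cell_surface_stats.csv`, `junction_stats.csv`), T1 events.
#' * `stats` — the comparison battery on the summaries (KS on deltas,
#'   Peacock on delta pairs, Pearson on pooled observations), written to
#'   `comparisons.csv`. Interface-flagged cells and interface junctions are
#'   excluded.
#' * `report` — summary medians/quartiles, quadrant fractions, 5°-binned
#'   orientation histogram, T1 counts, written to `report.json`.
#'
#' `all` runs every stage in order. Each invocation writes `manifest.json`
#' recording the tool version, full configuration, seeds and files, which
#' suffices to re-run the deterministic stages bit-identically.
#'
#' @param command One of `"simulate"`, `"preprocess"`, `"analyze"`,
#'   `"stats"`, `"report"`, `"all"`. Later stages expect earlier ones'
#'   outputs in `out_dir`.
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @param stats_seed Seed for the permutation p-values in the stats stage.
#' @param n_perm Permutations for the Peacock tests.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage artifacts produced in this
#'   call (including `manifest`).
#' @export
run_pipeline <- function(command = c("all", "simulate", "preprocess",
                                     "analyze", "stats", "report"),
                         config, out_dir, stats_seed = 1, n_perm = 999,
                         quiet = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- if (command == "all") {
    c("simulate", "preprocess", "analyze", "stats", "report")
  } else {
    command
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- list()
  ecfg <- embryo_config(
    movie = "sim_a", region = config$region,
    microns_per_pixel = config$microns_per_pixel, z_step_micron = 1,
    ap_axis_angle_deg = 90
  )
  for (stage in stages) {
    res <- tryCatch(
      switch(stage,
        simulate = stage_simulate(config, out_dir, say),
        preprocess = stage_preprocess(config, ecfg, out_dir, say),
        analyze = stage_analyze(config, ecfg, out_dir, say),
        stats = stage_stats(config, out_dir, stats_seed, n_perm, say),
        report = stage_report(config, out_dir, say)
      ),
      error = function(e) {
        abort_constrictr(sprintf("stage '%s' failed: %s", stage,
                                 conditionMessage(e)),
                         "constrictr_stage_error")
      }
    )
    artifacts[[stage]] <- res
  }
  manifest <- list(
    tool = "constrictr",
    version = as.character(utils::packageVersion("constrictr")),
    command = command,
    seeds = list(simulation = config$seed, stats = stats_seed),
    parameters = list(
      config = unclass(config),
      embryo_config = unclass(ecfg),
      preprocess = list(window = 7, min_cell_frames = 30,
                        min_junction_frames = 15),
      stats = list(n_perm = n_perm, peacock_mode = "full_grid",
                   exclude_interface = TRUE),
      t1 = list(k_stable = 5, pair_window = 3)
    ),
    files = list.files(out_dir),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts$manifest <- manifest
  invisible(artifacts)
}

stage_simulate <- function(config, out_dir, say) {
  say("simulate: %d cells x %d frames (seed %d)", config$n_cells,
      config$n_frames, config$seed)
  sim <- simulate_epithelium(config)
  write_tracking_tables(sim$dataset, out_dir)
  readr::write_csv(sim$adjacency, file.path(out_dir, "adjacency.csv"))
  truth_df <- tibble::tibble(
    track_id_cells = names(sim$truth$genotype),
    genotype = unname(sim$truth$genotype),
    regime = unname(sim$truth$regime)
  )
  readr::write_csv(truth_df, file.path(out_dir, "ground_truth.csv"))
  readr::write_csv(sim$truth$t1_events, file.path(out_dir, "scripted_t1.csv"))
  say("simulate: wrote %d cell rows, %d junction rows",
      nrow(sim$dataset$cell_surfaces), nrow(sim$dataset$junctions))
  sim
}

read_stage_tables <- function(out_dir) {
  suppressWarnings(read_tracking_tables(out_dir))
}

stage_preprocess <- function(config, ecfg, out_dir, say) {
  ds <- read_stage_tables(out_dir)
  ds <- preprocess_tables(ds, ecfg, quiet = TRUE)
  write_tracking_tables(ds, out_dir)
  say("preprocess: smoothed and standardized %d cell rows",
      nrow(ds$cell_surfaces %||% tibble::tibble()))
  ds
}

stage_analyze <- function(config, ecfg, out_dir, say) {
  ds <- read_stage_tables(out_dir)
  adjacency <- readr::read_csv(file.path(out_dir, "adjacency.csv"),
                               show_col_types = FALSE)
  calls <- call_genotype(ds$cell_surfaces, ecfg)
  labels <- setNames(calls$CRISPR, calls$track_id_cells)
  roster <- ds$cell_surfaces[, c("minute", "track_id_cells")]
  ncounts <- neighbor_counts(adjacency, labels, cells = roster)
  flags <- flag_interface(ncounts, labels)
  # refresh the label-dependent columns with the called genotypes
  cs <- ds$cell_surfaces
  cs$CRISPR <- unname(labels[cs$track_id_cells])
  cs <- cs |>
    dplyr::select(-dplyr::any_of(c("control_neighbors", "crispant_neighbors"))) |>
    dplyr::left_join(ncounts, by = c("minute", "track_id_cells"))
  ds$cell_surfaces <- cs[, intersect(names(cell_surfaces_cols), names(cs))]
  jx <- ds$junctions
  ab <- junction_cells(jx$track_id_junctions)
  jx$CRISPR <- classify_junction(unname(labels[ab$cell_a]),
                                 unname(labels[ab$cell_b]))
  ds$junctions <- jx
  ds <- summarize_tracks(ds, interface_flags = flags)
  t1 <- detect_t1(adjacency)
  write_tracking_tables(ds, out_dir)
  readr::write_csv(t1$events, file.path(out_dir, "t1_events.csv"))
  readr::write_csv(t1$counts, file.path(out_dir, "t1_counts.csv"))
  say("analyze: %d crispant calls, %d interface cells, %d stable T1 events",
      sum(labels == GENO_CRISPANT), sum(flags$at_mosaic_interface),
      nrow(t1$events))
  list(dataset = ds, calls = calls, flags = flags, t1 = t1)
}

# junction track ids are "j_<cellA>_<cellB>"
junction_cells <- function(track_id) {
  parts <- strsplit(track_id, "_", fixed = TRUE)
  tibble::tibble(
    cell_a = vapply(parts, `[`, "", 2),
    cell_b = vapply(parts, `[`, "", 3)
  )
}

default_comparisons <- function(has_crispants) {
  if (!has_crispants) {
    return(tibble::tibble(
      name = "area_vs_medial_actin_pooled", test = "pearson",
      variable = "medial_actin_standardized",
      variable2 = "apical_area_standardized",
      group_col = NA_character_, group_a = NA_character_,
      group_b = NA_character_
    ))
  }
  tibble::tibble(
    name = c("delta_area_control_vs_crispant",
             "delta_medial_actin_control_vs_crispant",
             "delta_area_vs_delta_medial_actin_2d",
             "area_vs_medial_actin_pooled"),
    test = c("ks", "ks", "peacock", "pearson"),
    variable = c("delta_apical_area", "delta_medial_actin",
                 "delta_medial_actin", "medial_actin_standardized"),
    variable2 = c(NA, NA, "delta_apical_area", "apical_area_standardized"),
    group_col = c("CRISPR", "CRISPR", "CRISPR", NA),
    group_a = c("control", "control", "control", NA),
    group_b = c("shroom3 crispant", "shroom3 crispant", "shroom3 crispant", NA)
  )
}

stage_stats <- function(config, out_dir, stats_seed, n_perm, say) {
  ds <- read_stage_tables(out_dir)
  stats_tab <- ds$cell_surface_stats
  keep <- !isTRUE_vec(stats_tab$at_mosaic_interface)
  stats_tab <- stats_tab[keep, ]
  has_cr <- "CRISPR" %in% names(stats_tab) &&
    length(unique(stats_tab$CRISPR[!is.na(stats_tab$CRISPR)])) > 1
  spec <- default_comparisons(has_cr)
  # pooled per-observation comparisons draw on the frame table, excluding
  # interface cells there as well
  obs <- ds$cell_surfaces
  obs <- obs[obs$track_id_cells %in% stats_tab$track_id_cells, ]
  results <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    dat <- if (s$test == "pearson") obs else stats_tab
    results[[i]] <- run_comparisons(dat, s, n_perm = n_perm,
                                    seed = stats_seed)
  }
  results <- dplyr::bind_rows(results)
  readr::write_csv(results, file.path(out_dir, "comparisons.csv"))
  say("stats: %d comparisons written", nrow(results))
  results
}

isTRUE_vec <- function(x) !is.na(x) & x

stage_report <- function(config, out_dir, say) {
  ds <- read_stage_tables(out_dir)
  stats_tab <- ds$cell_surface_stats
  stats_tab <- stats_tab[!isTRUE_vec(stats_tab$at_mosaic_interface), ]
  quart <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    list(q25 = q[1], median = q[2], q75 = q[3])
  }
  groups <- split(stats_tab, stats_tab$CRISPR)
  group_summaries <- lapply(groups, function(g) {
    list(n = nrow(g),
         delta_apical_area = quart(g$delta_apical_area),
         delta_medial_actin = quart(g$delta_medial_actin),
         start_area_micron = quart(g$start_area_micron),
         end_area_micron = quart(g$end_area_micron))
  })
  quad <- as.list(quadrant_fractions(stats_tab$delta_apical_area,
                                     stats_tab$delta_medial_actin))
  js <- ds$junction_stats
  orient_hist <- NULL
  if (!is.null(js) && nrow(js) > 0) {
    breaks <- seq(0, 90, by = 5)
    h <- graphics::hist(js$mean_orientation[!is.na(js$mean_orientation)],
                        breaks = breaks, plot = FALSE)
    orient_hist <- list(breaks_deg = breaks, counts = h$counts)
    js$orientation_class <- classify_orientation(js$mean_orientation)
  }
  comparisons <- NULL
  cmp_path <- file.path(out_dir, "comparisons.csv")
  if (file.exists(cmp_path)) {
    comparisons <- readr::read_csv(cmp_path, show_col_types = FALSE)
  }
  t1_counts <- NULL
  t1_path <- file.path(out_dir, "t1_counts.csv")
  if (file.exists(t1_path)) {
    t1 <- readr::read_csv(t1_path, show_col_types = FALSE)
    t1_counts <- list(total_events = sum(t1$t1_count) / 4,
                      cells_with_exchange = sum(t1$t1_count > 0))
  }
  report <- list(
    group_summaries = group_summaries,
    quadrant_percent_delta_area_vs_delta_medial_actin = quad,
    orientation_histogram = orient_hist,
    comparisons = comparisons,
    t1 = t1_counts
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  say("report: written report.json")
  report
}
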