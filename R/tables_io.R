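#' Construct a tracking dataset container
#'
#' Bundles the four tracking tables (`cell_surfaces`, `junctions`,
#' `cell_surface_stats`, `junction_stats`) into a single object. Any table
#' may be omitted; downstream stages operate on the tables that are present.
#'
#' @param cell_surfaces,junctions,cell_surface_stats,junction_stats Tibbles
#'   in the corresponding table schema, or `NULL`.
#' @return A `tracking_dataset` object (a named list of tibbles).
#' @export
tracking_dataset <- function(cell_surfaces = NULL, junctions = NULL,
                             cell_surface_stats = NULL, junction_stats = NULL) {
  out <- list(
    cell_surfaces = cell_surfaces,
    junctions = junctions,
    cell_surface_stats = cell_surface_stats,
    junction_stats = junction_stats
  )
  structure(out, class = "tracking_dataset")
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat("<tracking_dataset>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %-20s <absent>\n", nm))
    } else {
      cat(sprintf("  %-20s %d rows x %d cols\n", nm, nrow(x[[nm]]), ncol(x[[nm]])))
    }
  }
  invisible(x)
}

readr_type <- function(code) {
  switch(code,
    c = readr::col_character(),
    d = readr::col_double(),
    i = readr::col_integer(),
    l = readr::col_logical()
  )
}

read_one_table <- function(path, table) {
  schema <- table_schemas[[table]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  missing_mandatory <- setdiff(mandatory_cols[[table]], header)
  if (length(missing_mandatory) > 0) {
    abort_constrictr(
      sprintf("table '%s' (%s) lacks mandatory column(s): %s",
              table, path, paste(missing_mandatory, collapse = ", ")),
      "constrictr_schema_error"
    )
  }
  known <- intersect(names(schema), header)
  extra <- setdiff(header, names(schema))
  if (length(extra) > 0) {
    warning(sprintf("table '%s': preserving unknown column(s): %s",
                    table, paste(extra, collapse = ", ")), call. = FALSE)
  }
  spec <- lapply(schema[known], readr_type)
  spec <- c(spec, setNames(rep(list(readr::col_guess()), length(extra)), extra))
  df <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                        na = c("", "NA"), show_col_types = FALSE,
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_constrictr(
      sprintf("table '%s': unparseable value at row %d, column %d (expected %s, got '%s')",
              table, probs$row[1], probs$col[1], probs$expected[1], probs$actual[1]),
      "constrictr_parse_error"
    )
  }
  # canonical order: dictionary columns first (present ones), extras after
  df <- df[, c(known[order(match(known, names(schema)))], extra), drop = FALSE]
  attr(df, "missing_columns") <- setdiff(names(schema), header)
  df
}

#' Read tracking tables from CSV files
#'
#' Reads any subset of the four tracking tables from a directory (files named
#' `cell_surfaces.csv`, `junctions.csv`, `cell_surface_stats.csv`,
#' `junction_stats.csv`) or from an explicitly named list of paths. Columns
#' are type-coerced against the data dictionary; dictionary columns absent
#' from a file are recorded in the table's `missing_columns` attribute;
#' unknown extra columns are preserved with a warning. Empty cells and the
#' literal `NA` both parse as missing values, never as zero.
#'
#' @param paths Either a directory containing the CSV files, or a named
#'   character vector/list mapping table names to file paths.
#' @return A [tracking_dataset()].
#' @export
read_tracking_tables <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    files <- file.path(paths, paste0(names(table_schemas), ".csv"))
    names(files) <- names(table_schemas)
    files <- files[file.exists(files)]
  } else {
    files <- unlist(paths)
    bad <- setdiff(names(files), names(table_schemas))
    if (length(bad) > 0) {
      abort_constrictr(
        sprintf("unknown table name(s): %s", paste(bad, collapse = ", ")),
        "constrictr_schema_error"
      )
    }
  }
  if (length(files) == 0) {
    abort_constrictr("no tracking table files found", "constrictr_io_error")
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort_constrictr(
      sprintf("file not found: %s", paste(missing, collapse = ", ")),
      "constrictr_io_error"
    )
  }
  tabs <- lapply(names(files), function(nm) read_one_table(files[[nm]], nm))
  names(tabs) <- names(files)
  do.call(tracking_dataset, tabs)
}

#' Write tracking tables to CSV files
#'
#' Writes each present table to `<out_dir>/<table>.csv` with dictionary
#' column names and ordering. Missing values are serialized as empty strings;
#' doubles use shortest round-trip representation (at least 9 significant
#' digits survive a read/write cycle, and write-read-write is byte-stable).
#'
#' @param dataset A [tracking_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_tracking_tables <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_constrictr(sprintf("cannot create '%s'", out_dir), "constrictr_io_error")
  }
  written <- character()
  for (nm in names(dataset)) {
    if (is.null(dataset[[nm]])) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(dataset[[nm]], path, na = "")
    written[nm] <- path
  }
  invisible(written)
}

# per-track standardization check used by validate_tables()
check_standardized <- function(df, col, id_cols, table, tol = 1e-9) {
  if (!col %in% names(df)) return(NULL)
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      .mu = mean(.data[[col]][!is.na(.data[[col]])]),
      .sd = stats::sd(.data[[col]][!is.na(.data[[col]])]),
      .n = sum(!is.na(.data[[col]])),
      .row = dplyr::cur_group_rows()[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$.n >= 2,
                  abs(.data$.mu) > tol | abs(.data$.sd - 1) > tol)
  if (nrow(out) == 0) return(NULL)
  tibble::tibble(
    table = table, rule = sprintf("%s has per-track mean 0 and s.d. 1", col),
    row = out$.row,
    message = sprintf("track %s: mean %.3g, sd %.3g",
                      do.call(paste, c(out[id_cols], sep = "/")), out$.mu, out$.sd)
  )
}

violation <- function(table, rule, rows, messages) {
  if (length(rows) == 0) return(NULL)
  tibble::tibble(table = table, rule = rule, row = as.integer(rows),
                 message = messages)
}

#' Validate a tracking dataset against its schema invariants
#'
#' Checks every invariant of the table schemas: positive apical areas,
#' per-track standardized series with mean 0 and s.d. 1 (tolerance 1e-9),
#' strictly increasing frame index within tracks, region constant within a
#' movie, junction orientation in \[0, 90\], non-negative z-displacement,
#' corrected length at least the projected length, and mean orientation in
#' \[0, 90\]. Findings are returned as a report, never raised as errors.
#'
#' @param dataset A [tracking_dataset()].
#' @return A tibble with columns `table`, `rule`, `row`, `message`; zero rows
#'   if and only if every invariant holds.
#' @export
validate_tables <- function(dataset) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  reports <- list()
  cs <- dataset$cell_surfaces
  if (!is.null(cs)) {
    if ("apical_area_pixels" %in% names(cs)) {
      bad <- which(!is.na(cs$apical_area_pixels) & cs$apical_area_pixels <= 0)
      reports <- c(reports, list(violation(
        "cell_surfaces", "apical_area_pixels > 0", bad,
        sprintf("value %g", cs$apical_area_pixels[bad])
      )))
    }
    for (col in grep("_standardized$", names(cs), value = TRUE)) {
      reports <- c(reports, list(check_standardized(
        cs, col, c("movie", "track_id_cells"), "cell_surfaces"
      )))
    }
    reports <- c(reports, list(
      check_minute_increasing(cs, c("movie", "track_id_cells"), "cell_surfaces"),
      check_region_constant(cs, "cell_surfaces")
    ))
  }
  jx <- dataset$junctions
  if (!is.null(jx)) {
    if ("orientation" %in% names(jx)) {
      bad <- which(!is.na(jx$orientation) &
                     (jx$orientation < 0 | jx$orientation > 90))
      reports <- c(reports, list(violation(
        "junctions", "orientation in [0, 90]", bad,
        sprintf("value %g", jx$orientation[bad])
      )))
    }
    if ("delta_z_micron" %in% names(jx)) {
      bad <- which(!is.na(jx$delta_z_micron) & jx$delta_z_micron < 0)
      reports <- c(reports, list(violation(
        "junctions", "delta_z_micron >= 0", bad,
        sprintf("value %g", jx$delta_z_micron[bad])
      )))
    }
    if (all(c("length_corrected", "length_micron") %in% names(jx))) {
      ok <- !is.na(jx$length_corrected) & !is.na(jx$length_micron)
      bad <- which(ok & jx$length_corrected < jx$length_micron - 1e-9)
      reports <- c(reports, list(violation(
        "junctions", "length_corrected >= length_micron", bad,
        sprintf("corrected %g < projected %g",
                jx$length_corrected[bad], jx$length_micron[bad])
      )))
    }
    for (col in grep("_standardized$", names(jx), value = TRUE)) {
      reports <- c(reports, list(check_standardized(
        jx, col, c("movie", "track_id_junctions"), "junctions"
      )))
    }
    reports <- c(reports, list(
      check_minute_increasing(jx, c("movie", "track_id_junctions"), "junctions"),
      check_region_constant(jx, "junctions")
    ))
  }
  js <- dataset$junction_stats
  if (!is.null(js) && "mean_orientation" %in% names(js)) {
    bad <- which(!is.na(js$mean_orientation) &
                   (js$mean_orientation < 0 | js$mean_orientation > 90))
    reports <- c(reports, list(violation(
      "junction_stats", "mean_orientation in [0, 90]", bad,
      sprintf("value %g", js$mean_orientation[bad])
    )))
  }
  reports <- reports[!vapply(reports, is.null, TRUE)]
  if (length(reports) == 0) {
    return(tibble::tibble(table = character(), rule = character(),
                          row = integer(), message = character()))
  }
  dplyr::bind_rows(reports)
}

check_minute_increasing <- function(df, id_cols, table) {
  if (!"minute" %in% names(df)) return(NULL)
  bad <- df |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::mutate(.bad = c(FALSE, diff(.data$minute) <= 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.bad)
  if (nrow(bad) == 0) return(NULL)
  violation(table, "minute strictly increasing within track", bad$.row,
            sprintf("minute %d not after predecessor", bad$minute))
}

check_region_constant <- function(df, table) {
  if (!all(c("region", "movie") %in% names(df))) return(NULL)
  bad <- df |>
    dplyr::group_by(.data$movie) |>
    dplyr::summarise(.n = dplyr::n_distinct(.data$region),
                     .row = dplyr::cur_group_rows()[1], .groups = "drop") |>
    dplyr::filter(.data$.n > 1)
  if (nrow(bad) == 0) return(NULL)
  violation(table, "region constant within movie", bad$.row,
            sprintf("movie %s spans %d regions", bad$movie, bad$.n))
}
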