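#' Net change of a standardized track series
#'
#' The delta statistic is the last usable value minus the first usable
#' value of a per-track standardized series, summarizing net constriction
#' (negative for area) or net marker accumulation (positive) in s.d. units.
#'
#' @param values Numeric series for one track, in frame order.
#' @return Last minus first non-missing value, or `NA` when fewer than 2
#'   usable frames.
#' @export
delta_stat <- function(values) {
  usable <- which(!is.na(values))
  if (length(usable) < 2) return(NA_real_)
  values[usable[length(usable)]] - values[usable[1]]
}

first_usable <- function(values) {
  usable <- which(!is.na(values))
  if (length(usable) == 0) NA_real_ else values[usable[1]]
}
last_usable <- function(values) {
  usable <- which(!is.na(values))
  if (length(usable) == 0) NA_real_ else values[usable[length(usable)]]
}

#' Summarize tracks into per-track statistics tables
#'
#' Builds the `cell_surface_stats` and `junction_stats` tables from a
#' preprocessed dataset: initial/final smoothed micron areas, the five cell
#' delta statistics, the three junction delta statistics, mean junction
#' orientation, and (when supplied) the mosaic-interface flag.
#'
#' @param dataset A preprocessed [tracking_dataset()].
#' @param interface_flags Optional tibble (`movie` optional,
#'   `track_id_cells`, `at_mosaic_interface`) from [flag_interface()].
#' @return The dataset with `cell_surface_stats` and `junction_stats`
#'   replaced by freshly computed summaries.
#' @export
summarize_tracks <- function(dataset, interface_flags = NULL) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  cs <- dataset$cell_surfaces
  if (!is.null(cs) && nrow(cs) > 0) {
    delta_of <- function(col) {
      if (col %in% names(cs)) rlang::expr(delta_stat(.data[[!!col]])) else rlang::expr(NA_real_)
    }
    stats <- cs |>
      dplyr::group_by(.data$region, .data$movie, .data$track_id_cells) |>
      dplyr::arrange(.data$minute, .by_group = TRUE) |>
      dplyr::summarise(
        CRISPR = if ("CRISPR" %in% names(cs)) .data$CRISPR[1] else NA_character_,
        start_area_micron = !!(if ("apical_area_micron_smoothed" %in% names(cs))
          rlang::expr(first_usable(.data$apical_area_micron_smoothed)) else rlang::expr(NA_real_)),
        end_area_micron = !!(if ("apical_area_micron_smoothed" %in% names(cs))
          rlang::expr(last_usable(.data$apical_area_micron_smoothed)) else rlang::expr(NA_real_)),
        delta_apical_area = !!delta_of("apical_area_standardized"),
        delta_medial_actin = !!delta_of("medial_actin_standardized"),
        delta_junctional_actin = !!delta_of("junctional_actin_standardized"),
        delta_medial_Ncadherin = !!delta_of("medial_Ncadherin_standardized"),
        delta_junctional_Ncadherin = !!delta_of("junctional_Ncadherin_standardized"),
        .groups = "drop"
      )
    if (!is.null(interface_flags)) {
      by <- intersect(c("movie", "track_id_cells"), names(interface_flags))
      stats <- dplyr::left_join(stats, interface_flags, by = by)
    } else {
      stats$at_mosaic_interface <- NA
    }
    stats <- stats[, intersect(names(cell_surface_stats_cols), names(stats))]
    dataset$cell_surface_stats <- stats
  }
  jx <- dataset$junctions
  if (!is.null(jx) && nrow(jx) > 0) {
    delta_of <- function(col) {
      if (col %in% names(jx)) rlang::expr(delta_stat(.data[[!!col]])) else rlang::expr(NA_real_)
    }
    jstats <- jx |>
      dplyr::group_by(.data$region, .data$movie, .data$track_id_junctions) |>
      dplyr::arrange(.data$minute, .by_group = TRUE) |>
      dplyr::summarise(
        CRISPR = if ("CRISPR" %in% names(jx)) .data$CRISPR[1] else NA_character_,
        delta_length = !!delta_of("length_standardized"),
        delta_actin = !!delta_of("actin_standardized"),
        delta_Ncadherin = !!delta_of("Ncadherin_standardized"),
        mean_orientation = !!(if ("orientation" %in% names(jx))
          rlang::expr(mean(.data$orientation, na.rm = TRUE)) else rlang::expr(NA_real_)),
        .groups = "drop"
      )
    jstats <- jstats[, intersect(names(junction_stats_cols), names(jstats))]
    dataset$junction_stats <- jstats
  }
  dataset
}

#' Quadrant fractions of a paired delta scatter
#'
#' Percentage of tracks falling in each quadrant of the (x, y) delta plane,
#' with zero values counted in the non-negative quadrants. The four
#' percentages sum to 100.
#'
#' @param x,y Paired numeric vectors of per-track deltas.
#' @return Named numeric vector of percentages:
#'   `x_neg_y_neg`, `x_neg_y_pos`, `x_pos_y_neg`, `x_pos_y_pos`
#'   (`pos` meaning >= 0).
#' @export
quadrant_fractions <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) {
    abort_constrictr("no complete (x, y) pairs", "constrictr_parameter_error")
  }
  n <- length(x)
  c(
    x_neg_y_neg = 100 * sum(x < 0 & y < 0) / n,
    x_neg_y_pos = 100 * sum(x < 0 & y >= 0) / n,
    x_pos_y_neg = 100 * sum(x >= 0 & y < 0) / n,
    x_pos_y_pos = 100 * sum(x >= 0 & y >= 0) / n
  )
}

# run-length structure of a pair's presence across the frame span
pair_runs <- function(present) {
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  list(values = r$values, starts = starts, ends = ends, lengths = r$lengths)
}

#' Detect stable T1 neighbor exchanges
#'
#' A T1 transition is scored when one cell pair (A, B) loses its shared
#' junction and an orthogonal pair (C, D) gains one: the loss must persist
#' at least `k_stable` frames, the gain must begin within `pair_window`
#' frames of the loss and also persist at least `k_stable` frames, and C
#' and D must both be neighbors of A and of B at the last frame of the
#' (A, B) contact. Each stable event increments the per-cell exchange count
#' of all four participating cells.
#'
#' @param adjacency Tibble of per-frame adjacencies (`minute`, `cell_a`,
#'   `cell_b`; unordered pairs).
#' @param k_stable Minimum persistence, in frames, of both the loss and the
#'   gain (default 5).
#' @param pair_window Maximum offset, in frames, between loss and gain
#'   (default 3), tolerating the transient 4-fold vertex.
#' @return List with `events` (tibble: `cell_a`, `cell_b`, `cell_c`,
#'   `cell_d`, `loss_frame`, `gain_frame`, `stable`) and `counts` (tibble:
#'   `track_id_cells`, `t1_count`).
#' @export
detect_t1 <- function(adjacency, k_stable = 5, pair_window = 3) {
  frames <- sort(unique(adjacency$minute))
  cells <- unique(c(adjacency$cell_a, adjacency$cell_b))
  counts <- setNames(integer(length(cells)), cells)
  events <- list()
  if (length(frames) >= 2 && nrow(adjacency) > 0) {
    f_index <- match(adjacency$minute, frames)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    pair_key <- key(adjacency$cell_a, adjacency$cell_b)
    pairs <- unique(pair_key)
    n_f <- length(frames)
    # presence matrix pair x frame
    pres <- matrix(FALSE, length(pairs), n_f, dimnames = list(pairs, NULL))
    pres[cbind(match(pair_key, pairs), f_index)] <- TRUE
    # neighbor sets per frame for the common-neighbor requirement
    neigh_at <- function(cell, f) {
      rows <- f_index == f & (adjacency$cell_a == cell | adjacency$cell_b == cell)
      setdiff(unique(c(adjacency$cell_a[rows], adjacency$cell_b[rows])), cell)
    }
    # losses: present run followed by absence lasting >= k_stable (or to end)
    gains <- list()  # per pair: frames where a stable gain starts
    losses <- list()
    for (p in seq_along(pairs)) {
      r <- pair_runs(pres[p, ])
      for (i in seq_along(r$values)) {
        if (!r$values[i] && i > 1 && r$lengths[i] >= k_stable) {
          losses[[length(losses) + 1]] <- list(pair = pairs[p], f = r$starts[i])
        }
        if (r$values[i] && i > 1 && r$lengths[i] >= k_stable) {
          gains[[length(gains) + 1]] <- list(pair = pairs[p], f = r$starts[i])
        }
      }
    }
    for (ls in losses) {
      ab <- strsplit(ls$pair, "\r", fixed = TRUE)[[1]]
      loss_f <- ls$f                      # first frame of absence
      contact_f <- loss_f - 1             # last frame with the junction
      na_ <- neigh_at(ab[1], contact_f)
      nb_ <- neigh_at(ab[2], contact_f)
      common <- setdiff(intersect(na_, nb_), ab)
      if (length(common) < 2) next
      for (g in gains) {
        cd <- strsplit(g$pair, "\r", fixed = TRUE)[[1]]
        if (!all(cd %in% common)) next
        if (abs(g$f - loss_f) > pair_window) next
        events[[length(events) + 1]] <- tibble::tibble(
          cell_a = ab[1], cell_b = ab[2], cell_c = cd[1], cell_d = cd[2],
          loss_frame = frames[loss_f],
          gain_frame = frames[g$f], stable = TRUE
        )
        counts[c(ab, cd)] <- counts[c(ab, cd)] + 1L
        break
      }
    }
  }
  events <- if (length(events) == 0) {
    tibble::tibble(cell_a = character(), cell_b = character(),
                   cell_c = character(), cell_d = character(),
                   loss_frame = numeric(), gain_frame = numeric(),
                   stable = logical())
  } else {
    dplyr::bind_rows(events)
  }
  list(
    events = events,
    counts = tibble::tibble(track_id_cells = names(counts),
                            t1_count = unname(counts))
  )
}
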