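# Genotype labels used throughout
GENO_CONTROL <- "control"
GENO_CRISPANT <- "shroom3 crispant"
GENO_INTERFACE <- "at mosaic interface"

#' Otsu threshold (between-class variance maximization)
#'
#' Histogram-based automatic threshold: values are binned (default 256
#' bins) and the cut maximizing the between-class variance of the two
#' resulting classes is returned.
#'
#' @param x Numeric values.
#' @param n_bins Number of histogram bins.
#' @return The threshold value (lower edge of the first "high" bin), plus
#'   attributes `separation` (distance of class means in pooled
#'   within-class s.d. units) and `eta` (between/total variance ratio).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0) {
    abort_constrictr("need at least two distinct finite values",
                     "constrictr_parameter_error")
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  mu_t <- sum(w * mids)
  w0 <- cumsum(w)[-n_bins]
  mu0c <- cumsum(w * mids)[-n_bins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0c[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sigma_b)
  thr <- edges[k + 1]
  lo <- x[x < thr]; hi <- x[x >= thr]
  sep <- if (length(lo) > 1 && length(hi) > 1) {
    (mean(hi) - mean(lo)) / (stats::sd(lo) + stats::sd(hi))
  } else {
    Inf
  }
  structure(thr,
            separation = sep,
            eta = max(sigma_b) / sum(w * (mids - mu_t)^2))
}

#' Call control vs crispant genotype per cell track
#'
#' Each cell's genotype score is the track-mean of its medial membrane-BFP
#' intensity (genotype is a lineage property, so one label per track). A
#' cell is called a crispant when its score is at or above the embryo's BFP
#' threshold. The threshold is the config's `bfp_threshold` when given,
#' otherwise an automatic bimodal split (Otsu's between-class-variance
#' maximization on the log10 score histogram, 256 bins). Manual
#' `genotype_overrides` in the config are applied last and always win.
#'
#' If the automatic split finds no convincing bimodality (class means
#' closer than 2 pooled within-class s.d.), all cells fall back to
#' `"control"` with a warning, and the result is flagged.
#'
#' @param cell_surfaces The `cell_surfaces` tibble (one movie; must carry
#'   `medial_memBFP`).
#' @param config The movie's [embryo_config()].
#' @param score_col Column to score on (default `"medial_memBFP"`).
#' @return Tibble with `movie`, `track_id_cells`, `bfp_score`, `CRISPR`,
#'   and `source` (`"threshold"` or `"override"`); attributes `threshold`
#'   and `degenerate` record the split used.
#' @export
call_genotype <- function(cell_surfaces, config,
                          score_col = "medial_memBFP") {
  stopifnot(inherits(config, "embryo_config"))
  df <- cell_surfaces[cell_surfaces$movie == config$movie, , drop = FALSE]
  if (nrow(df) == 0) {
    abort_constrictr(sprintf("no cells for movie '%s'", config$movie),
                     "constrictr_config_error")
  }
  if (!score_col %in% names(df)) {
    abort_constrictr(sprintf("column '%s' absent", score_col),
                     "constrictr_schema_error")
  }
  scores <- df |>
    dplyr::group_by(.data$movie, .data$track_id_cells) |>
    dplyr::summarise(bfp_score = mean(.data[[score_col]], na.rm = TRUE),
                     .groups = "drop")
  degenerate <- FALSE
  if (!is.null(config$bfp_threshold)) {
    thr <- config$bfp_threshold
  } else {
    log_scores <- log10(pmax(scores$bfp_score, .Machine$double.eps))
    auto <- otsu_threshold(log_scores)
    if (attr(auto, "separation") < 2) {
      warning(sprintf("movie '%s': BFP score distribution not convincingly bimodal; all cells labeled control (supply bfp_threshold or overrides)",
                      config$movie), call. = FALSE)
      degenerate <- TRUE
      thr <- Inf
    } else {
      thr <- 10^as.numeric(auto)
    }
  }
  scores$CRISPR <- ifelse(scores$bfp_score >= thr, GENO_CRISPANT, GENO_CONTROL)
  scores$CRISPR[is.na(scores$bfp_score)] <- NA_character_
  scores$source <- "threshold"
  ov <- config$genotype_overrides
  if (length(ov) > 0) {
    bad <- setdiff(unlist(ov), c(GENO_CONTROL, GENO_CRISPANT))
    if (length(bad) > 0) {
      abort_constrictr(sprintf("invalid override label(s): %s",
                               paste(unique(bad), collapse = ", ")),
                       "constrictr_config_error")
    }
    hit <- match(scores$track_id_cells, names(ov))
    scores$CRISPR[!is.na(hit)] <- unlist(ov)[hit[!is.na(hit)]]
    scores$source[!is.na(hit)] <- "override"
  }
  attr(scores, "threshold") <- thr
  attr(scores, "degenerate") <- degenerate
  scores
}

#' Per-frame neighbor genotype counts
#'
#' @param adjacency Tibble of per-frame cell adjacencies with columns
#'   `minute`, `cell_a`, `cell_b` (unordered pairs sharing a junction).
#' @param labels Named character vector mapping cell track id to
#'   `"control"` / `"shroom3 crispant"`.
#' @param cells Optional tibble (`minute`, `track_id_cells`) giving the full
#'   cell roster per frame, so isolated cells report (0, 0) counts. Defaults
#'   to the cells appearing in `adjacency`.
#' @return Tibble with `minute`, `track_id_cells`, `control_neighbors`,
#'   `crispant_neighbors`.
#' @export
neighbor_counts <- function(adjacency, labels, cells = NULL) {
  unlabeled <- setdiff(unique(c(adjacency$cell_a, adjacency$cell_b)),
                       names(labels))
  if (length(unlabeled) > 0) {
    abort_constrictr(sprintf("unlabeled cell(s) in adjacency: %s",
                             paste(head(unlabeled, 5), collapse = ", ")),
                     "constrictr_label_error")
  }
  # each pair contributes to both members' counts
  long <- dplyr::bind_rows(
    tibble::tibble(minute = adjacency$minute, track_id_cells = adjacency$cell_a,
                   neighbor = adjacency$cell_b),
    tibble::tibble(minute = adjacency$minute, track_id_cells = adjacency$cell_b,
                   neighbor = adjacency$cell_a)
  )
  long$neighbor_label <- unname(labels[long$neighbor])
  counts <- long |>
    dplyr::group_by(.data$minute, .data$track_id_cells) |>
    dplyr::summarise(
      control_neighbors = sum(.data$neighbor_label == GENO_CONTROL),
      crispant_neighbors = sum(.data$neighbor_label == GENO_CRISPANT),
      .groups = "drop"
    )
  if (!is.null(cells)) {
    counts <- cells |>
      dplyr::distinct(.data$minute, .data$track_id_cells) |>
      dplyr::left_join(counts, by = c("minute", "track_id_cells")) |>
      dplyr::mutate(
        control_neighbors = dplyr::coalesce(.data$control_neighbors, 0L),
        crispant_neighbors = dplyr::coalesce(.data$crispant_neighbors, 0L)
      )
  }
  counts
}

#' Flag cells at the mosaic interface
#'
#' A cell is at the mosaic interface when, at any frame of its track, it
#' had at least one neighbor of the opposite genotype. Such cells are
#' excluded from quantitative comparisons by downstream stages.
#'
#' @param counts Output of [neighbor_counts()].
#' @param labels Named genotype vector (as for [neighbor_counts()]).
#' @return Tibble with `track_id_cells`, `at_mosaic_interface`.
#' @export
flag_interface <- function(counts, labels) {
  lab <- unname(labels[counts$track_id_cells])
  opposite <- ifelse(lab == GENO_CONTROL,
                     counts$crispant_neighbors, counts$control_neighbors)
  counts |>
    dplyr::mutate(.opp = opposite) |>
    dplyr::group_by(.data$track_id_cells) |>
    dplyr::summarise(at_mosaic_interface = any(.data$.opp > 0, na.rm = TRUE),
                     .groups = "drop")
}

#' Classify a junction's CRISPR status from its flanking cells
#'
#' A junction between two control cells is `"control"`, between two
#' crispant cells `"shroom3 crispant"`, and between one of each
#' `"at mosaic interface"` (symmetric in its arguments). Interface
#' junctions are excluded from quantitative comparisons.
#'
#' @param label_a,label_b Genotype labels of the two flanking cells
#'   (vectorized).
#' @return Character vector of junction statuses.
#' @export
#' @examples
#' classify_junction("control", "shroom3 crispant") # "at mosaic interface"
classify_junction <- function(label_a, label_b) {
  valid <- c(GENO_CONTROL, GENO_CRISPANT)
  bad <- setdiff(unique(c(label_a, label_b)), c(valid, NA))
  if (length(bad) > 0) {
    abort_constrictr(sprintf("unknown genotype label(s): %s",
                             paste(bad, collapse = ", ")),
                     "constrictr_label_error")
  }
  dplyr::case_when(
    is.na(label_a) | is.na(label_b) ~ NA_character_,
    label_a == label_b & label_a == GENO_CONTROL ~ GENO_CONTROL,
    label_a == label_b ~ GENO_CRISPANT,
    TRUE ~ GENO_INTERFACE
  )
}
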