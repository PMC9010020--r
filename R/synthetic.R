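#' Configuration for the synthetic mosaic epithelium generator
#'
#' Defines the study conditions emulated by [simulate_epithelium()]: a
#' mosaic sheet of tracked polygonal cells whose apical areas follow
#' region-specific trajectories (gradual constriction in anterior-like
#' tissue; late, rapid constriction mixed with dilation in posterior-like
#' tissue), fluorescence channels coupled to standardized area with
#' configurable target correlation and AR(1) noise, bimodal membrane-BFP by
#' genotype, and scripted T1 neighbor exchanges.
#'
#' @param n_cells Number of cells (>= 4).
#' @param n_frames Number of frames (1 frame = 1 minute).
#' @param seed Mandatory integer seed; identical config + seed gives
#'   byte-identical tables.
#' @param region `"anterior"` or `"posterior"` regime.
#' @param crispant_fraction Fraction of cells that are crispant, patterned
#'   as a half-plane mosaic (largest-x side of the sheet).
#' @param trajectory Per-genotype area-trajectory parameters; see Details.
#' @param coupling Per-genotype target correlations of medial/junctional
#'   actin and N-cadherin with standardized apical area (negative values:
#'   marker rises as area falls).
#' @param noise_sd Marginal s.d. of the AR(1) intensity noise, in units of
#'   the standardized signal.
#' @param noise_rho AR(1) autocorrelation of the intensity noise.
#' @param bfp_control_mean,bfp_crispant_mean,bfp_sd Membrane-BFP intensity
#'   modes by genotype, arbitrary units.
#' @param t1_frames Integer vector of frames at which to script one T1
#'   neighbor exchange each.
#' @param microns_per_pixel Pixel size, µm/px.
#' @param z_amp_micron Maximum per-junction z-displacement, µm.
#' @param hex_radius Hexagon circumradius in pixels (sets cell size).
#' @param jitter_frac Vertex jitter as a fraction of `hex_radius`.
#'
#' @details
#' `trajectory` is a list with `control` and `crispant` entries, each a
#' list with `constrict_fraction` (share of cells that constrict),
#' `ratio` (final/initial area of constricting cells), `onset_frac`
#' (fraction of the movie elapsed before constriction begins; anterior-like
#' constriction is gradual from the start, posterior-like starts around 75%
#' through), and `dilate_range` (range of final/initial ratios for the
#' non-constricting cells). The defaults depend on `region` and are chosen
#' to mirror the qualitative regional behaviors: nearly all anterior
#' control cells constrict gradually; anterior crispants mostly dilate;
#' posterior cells mix late rapid constriction with drift/dilation.
#'
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_cells = 150, n_frames = 60, seed,
                             region = c("anterior", "posterior"),
                             crispant_fraction = 0,
                             trajectory = NULL, coupling = NULL,
                             noise_sd = 1, noise_rho = 0.8,
                             bfp_control_mean = 100, bfp_crispant_mean = 1000,
                             bfp_sd = 50,
                             t1_frames = integer(),
                             microns_per_pixel = 0.5, z_amp_micron = 2,
                             hex_radius = 10, jitter_frac = 0.15) {
  region <- match.arg(region)
  if (missing(seed) || is.null(seed)) {
    abort_constrictr("a seed is mandatory for the synthetic generator",
                     "constrictr_config_error")
  }
  if (n_cells < 4) {
    abort_constrictr("n_cells must be at least 4", "constrictr_config_error")
  }
  if (crispant_fraction < 0 || crispant_fraction > 1) {
    abort_constrictr("crispant_fraction must lie in [0, 1]",
                     "constrictr_config_error")
  }
  default_traj <- list(
    anterior = list(
      control = list(constrict_fraction = 0.95, ratio = 0.5,
                     onset_frac = 0, dilate_range = c(1.05, 1.2)),
      crispant = list(constrict_fraction = 0.3, ratio = 0.8,
                      onset_frac = 0, dilate_range = c(1.1, 1.5))
    ),
    posterior = list(
      control = list(constrict_fraction = 0.6, ratio = 0.45,
                     onset_frac = 0.75, dilate_range = c(0.9, 1.25)),
      crispant = list(constrict_fraction = 0.5, ratio = 0.55,
                      onset_frac = 0.75, dilate_range = c(0.9, 1.3))
    )
  )
  default_coupling <- list(
    anterior = list(control = c(actin = -0.7, Ncadherin = -0.6),
                    crispant = c(actin = -0.2, Ncadherin = -0.05)),
    posterior = list(control = c(actin = -0.4, Ncadherin = 0),
                     crispant = c(actin = -0.3, Ncadherin = 0))
  )
  trajectory <- trajectory %||% default_traj[[region]]
  coupling <- coupling %||% default_coupling[[region]]
  for (g in c("control", "crispant")) {
    if (any(abs(coupling[[g]]) >= 1)) {
      abort_constrictr("target correlations must have magnitude < 1",
                       "constrictr_config_error")
    }
    if (trajectory[[g]]$ratio <= 0) {
      abort_constrictr("area ratios must be positive", "constrictr_config_error")
    }
  }
  structure(
    list(n_cells = n_cells, n_frames = n_frames, seed = as.integer(seed),
         region = region, crispant_fraction = crispant_fraction,
         trajectory = trajectory, coupling = coupling,
         noise_sd = noise_sd, noise_rho = noise_rho,
         bfp_control_mean = bfp_control_mean,
         bfp_crispant_mean = bfp_crispant_mean, bfp_sd = bfp_sd,
         t1_frames = as.integer(t1_frames),
         microns_per_pixel = microns_per_pixel,
         z_amp_micron = z_amp_micron,
         hex_radius = hex_radius, jitter_frac = jitter_frac),
    class = "synthetic_config"
  )
}

#' Build a jittered hexagonal tessellation with shared vertices
#'
#' Deterministic for a given config seed: a honeycomb of flat-top hexagons
#' sized to hold `n_cells`, with each vertex jittered once (vertices are
#' shared objects, so every interior edge is bordered by exactly two
#' cells).
#'
#' @param config A [synthetic_config()].
#' @return List with `vertices` (matrix x, y in px), `cells` (list of
#'   ordered vertex-id vectors), `edges` (tibble `cell_a`, `cell_b`, `v1`,
#'   `v2` of shared edges), `cell_ids` (character labels).
#' @export
build_mesh <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cells
  s <- config$hex_radius
  n_col <- ceiling(sqrt(n))
  n_row <- ceiling(n / n_col)
  ang <- (0:5) * pi / 3
  vx_off <- s * cos(ang)
  vy_off <- s * sin(ang)
  vkey <- character(); vx <- numeric(); vy <- numeric()
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  cells <- vector("list", n_row * n_col)
  k <- 0
  for (q in 0:(n_col - 1)) {
    for (r in 0:(n_row - 1)) {
      k <- k + 1
      if (k > n) break
      cx <- 1.5 * s * q
      cy <- sqrt(3) * s * (r + 0.5 * (q %% 2))
      ids <- integer(6)
      for (m in 1:6) {
        x <- cx + vx_off[m]; y <- cy + vy_off[m]
        key <- sprintf("%.3f_%.3f", x, y)
        id <- vmap[[key]]
        if (is.null(id)) {
          vx <- c(vx, x); vy <- c(vy, y)
          id <- length(vx)
          assign(key, id, envir = vmap)
        }
        ids[m] <- id
      }
      cells[[k]] <- ids
    }
  }
  cells <- cells[seq_len(min(k, n))]
  n <- length(cells)
  verts <- cbind(x = vx, y = vy)
  # one jitter draw per shared vertex
  j <- config$jitter_frac * s
  verts <- verts + matrix(stats::runif(2 * nrow(verts), -j, j), ncol = 2)
  verts[, 1] <- verts[, 1] - min(verts[, 1]) + 2
  verts[, 2] <- verts[, 2] - min(verts[, 2]) + 2
  # edges: unordered vertex pairs appearing in cell outlines
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_owner <- list()
  for (ci in seq_len(n)) {
    ids <- cells[[ci]]
    for (m in 1:6) {
      ek <- edge_key(ids[m], ids[m %% 6 + 1])
      edge_owner[[ek]] <- c(edge_owner[[ek]], ci)
    }
  }
  shared <- edge_owner[vapply(edge_owner, length, 1L) == 2]
  vpairs <- do.call(rbind, strsplit(names(shared), " ", fixed = TRUE))
  edges <- tibble::tibble(
    cell_a = vapply(shared, `[`, 1L, 1), cell_b = vapply(shared, `[`, 2L, 2),
    v1 = as.integer(vpairs[, 1]), v2 = as.integer(vpairs[, 2])
  )
  edges <- edges[order(edges$cell_a, edges$cell_b), ]
  list(vertices = verts, cells = cells, edges = edges,
       cell_ids = sprintf("c%03d", seq_len(n)),
       n_boundary_edges = sum(vapply(edge_owner, length, 1L) == 1))
}

# vectorized shoelace area for all cells (X, Y are n_cells x 6 matrices)
hex_areas <- function(X, Y) {
  a <- 0
  for (m in 1:6) {
    m2 <- m %% 6 + 1
    a <- a + X[, m] * Y[, m2] - X[, m2] * Y[, m]
  }
  abs(a) / 2
}

# AR(1) noise matrix (n_series x n_steps) with unit marginal sd, scaled
ar1_noise <- function(n_series, n_steps, rho, sd) {
  innov <- matrix(stats::rnorm(n_series * n_steps), n_series, n_steps)
  out <- matrix(0, n_series, n_steps)
  out[, 1] <- innov[, 1]
  if (n_steps > 1) {
    w <- sqrt(1 - rho^2)
    for (t in 2:n_steps) out[, t] <- rho * out[, t - 1] + w * innov[, t]
  }
  out * sd
}

# s.d. retention factor of a centered w-frame moving average applied to
# AR(1) noise with autocorrelation rho (interior-window formula):
# var = (w + 2 * sum_{k=1}^{w-1} (w - k) rho^k) / w^2.
# The coupling parameter targets the correlation of the *analyzed* series
# (7-frame smoothed, per-track standardized), so the generator inflates its
# noise by 1/retention to counter the smoothing attenuation.
smoothing_sd_retention <- function(window, rho) {
  k <- seq_len(window - 1)
  sqrt((window + 2 * sum((window - k) * rho^k)) / window^2)
}

# standardize rows of a matrix (population of per-track z-scores)
row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  s[s == 0] <- 1
  (m - mu) / s
}

#' Simulate a tracked mosaic epithelium time-lapse
#'
#' Generates cell and junction tables in the tracking-table schema with
#' full ground truth. Vertex positions evolve by iterative per-cell area
#' targeting (each cell's target area follows its regime trajectory and
#' shared vertices relax toward the targets), so areas, junction lengths
#' and orientations co-vary consistently. Intensities are a regime/genotype
#' baseline plus the configured coupling times the negated standardized
#' area plus AR(1) noise; membrane-BFP is drawn from the genotype's mode;
#' scripted T1 events are executed by edge collapse and orthogonal
#' re-expansion.
#'
#' @param config A [synthetic_config()].
#' @param movie Movie/embryo label for the emitted tables.
#' @return List with `dataset` (a [tracking_dataset()] carrying raw
#'   `cell_surfaces` and `junctions` tables), `adjacency` (per-frame pair
#'   tibble for T1 detection), `truth` (ground-truth list), `positions`
#'   (vertex coordinate array, frames x vertices x 2, for rendering),
#'   `mesh`, and `config`.
#' @export
simulate_epithelium <- function(config, movie = "sim_a") {
  stopifnot(inherits(config, "synthetic_config"))
  mesh <- build_mesh(config)          # seeds the RNG with config$seed
  n <- length(mesh$cells)
  n_f <- config$n_frames
  idx <- do.call(rbind, mesh$cells)   # n x 6 vertex ids
  V <- mesh$vertices

  # --- genotype: half-plane mosaic on initial centroid x ---
  cx0 <- rowMeans(matrix(V[idx, 1], n, 6))
  genotype <- rep(GENO_CONTROL, n)
  if (config$crispant_fraction > 0) {
    cut <- stats::quantile(cx0, 1 - config$crispant_fraction, names = FALSE)
    genotype[cx0 > cut] <- GENO_CRISPANT
  }

  # --- per-cell target area trajectories ---
  A0 <- hex_areas(matrix(V[idx, 1], n, 6), matrix(V[idx, 2], n, 6))
  log_mult <- matrix(0, n, n_f)
  regime <- character(n)
  for (g in c("control", "crispant")) {
    tr <- config$trajectory[[g]]
    lab <- if (g == "control") GENO_CONTROL else GENO_CRISPANT
    members <- which(genotype == lab)
    if (length(members) == 0) next
    n_con <- round(tr$constrict_fraction * length(members))
    constrictors <- members[seq_len(n_con)]
    dilators <- setdiff(members, constrictors)
    regime[constrictors] <- paste0(g, "_constrict")
    regime[dilators] <- paste0(g, "_dilate")
    onset <- max(1, round(tr$onset_frac * n_f))
    ramp <- pmax(0, (seq_len(n_f) - onset)) / max(1, n_f - onset)
    for (ci in constrictors) {
      log_mult[ci, ] <- log(tr$ratio) * ramp
    }
    if (length(dilators) > 0) {
      ratios <- stats::runif(length(dilators), tr$dilate_range[1],
                             tr$dilate_range[2])
      for (i in seq_along(dilators)) {
        log_mult[dilators[i], ] <- log(ratios[i]) * seq_len(n_f) / n_f
      }
    }
  }
  A_target <- A0 * exp(log_mult)

  # --- vertex relaxation toward per-cell area targets ---
  n_v <- nrow(V)
  flat_idx <- as.vector(idx)
  positions <- array(NA_real_, c(n_f, n_v, 2))
  areas <- matrix(NA_real_, n, n_f)
  Vt <- V
  for (t in seq_len(n_f)) {
    for (it in 1:4) {
      X <- matrix(Vt[idx, 1], n, 6)
      Y <- matrix(Vt[idx, 2], n, 6)
      cur <- hex_areas(X, Y)
      f <- sqrt(A_target[, t] / cur)
      f <- pmin(pmax(f, 0.8), 1.25)   # bounded step keeps polygons simple
      cxm <- rowMeans(X); cym <- rowMeans(Y)
      px <- cxm + f * (X - cxm)
      py <- cym + f * (Y - cym)
      dx <- rowsum(as.vector(px - X), flat_idx)
      dy <- rowsum(as.vector(py - Y), flat_idx)
      cnt <- rowsum(rep(1, length(flat_idx)), flat_idx)
      ids <- as.integer(rownames(dx))
      Vt[ids, 1] <- Vt[ids, 1] + 0.6 * dx / cnt
      Vt[ids, 2] <- Vt[ids, 2] + 0.6 * dy / cnt
    }
    positions[t, , ] <- Vt
    areas[, t] <- hex_areas(matrix(Vt[idx, 1], n, 6), matrix(Vt[idx, 2], n, 6))
  }

  # --- intensities coupled to negated standardized area ---
  z_area <- row_standardize(areas)
  retention <- smoothing_sd_retention(7, config$noise_rho)
  mk_channel <- function(target_r, base, amp) {
    r <- matrix(rep(target_r, n_f), n, n_f)
    noise <- ar1_noise(n, n_f, config$noise_rho, config$noise_sd)
    signal <- r * z_area + (sqrt(pmax(0, 1 - r^2)) / retention) * noise
    base * (1 + amp * signal)
  }
  r_act <- ifelse(genotype == GENO_CONTROL,
                  config$coupling$control["actin"],
                  config$coupling$crispant["actin"])
  r_ncad <- ifelse(genotype == GENO_CONTROL,
                   config$coupling$control["Ncadherin"],
                   config$coupling$crispant["Ncadherin"])
  medial_actin <- mk_channel(r_act, 500, 0.15)
  junctional_actin <- mk_channel(r_act, 650, 0.15)
  medial_Ncadherin <- mk_channel(r_ncad, 400, 0.15)
  junctional_Ncadherin <- mk_channel(r_ncad, 550, 0.15)
  bfp_mode <- ifelse(genotype == GENO_CRISPANT,
                     config$bfp_crispant_mean, config$bfp_control_mean)
  medial_memBFP <- bfp_mode + ar1_noise(n, n_f, config$noise_rho, config$bfp_sd)
  junctional_memBFP <- 1.2 * bfp_mode +
    ar1_noise(n, n_f, config$noise_rho, config$bfp_sd)

  # --- adjacency over time, with scripted T1 events ---
  ids <- mesh$cell_ids
  edges <- mesh$edges
  base_adj <- tibble::tibble(cell_a = ids[as.integer(edges$cell_a)],
                             cell_b = ids[as.integer(edges$cell_b)],
                             v1 = edges$v1, v2 = edges$v2)
  events <- script_t1_events(config, mesh, base_adj)
  adj_frames <- vector("list", n_f)
  for (t in seq_len(n_f)) {
    adj <- base_adj[, c("cell_a", "cell_b")]
    for (e in events) {
      if (t >= e$frame) {
        drop <- (adj$cell_a == e$ab[1] & adj$cell_b == e$ab[2]) |
          (adj$cell_a == e$ab[2] & adj$cell_b == e$ab[1])
        adj <- adj[!drop, ]
        adj <- dplyr::bind_rows(adj, tibble::tibble(
          cell_a = min(e$cd), cell_b = max(e$cd)))
      }
    }
    adj$minute <- t
    adj_frames[[t]] <- adj
  }
  adjacency <- dplyr::bind_rows(adj_frames)[, c("minute", "cell_a", "cell_b")]

  # --- neighbor genotype counts per frame ---
  labels <- setNames(genotype, ids)
  roster <- tidyr::expand_grid(minute = seq_len(n_f), track_id_cells = ids)
  ncounts <- neighbor_counts(adjacency, labels, cells = roster)

  # --- cell table ---
  cell_rows <- vector("list", n_f)
  for (t in seq_len(n_f)) {
    Xt <- matrix(positions[t, idx, 1], n, 6)
    Yt <- matrix(positions[t, idx, 2], n, 6)
    vx_strings <- vapply(seq_len(n), function(ci) {
      encode_vertices(cbind(Xt[ci, ], Yt[ci, ]))
    }, "")
    cell_rows[[t]] <- tibble::tibble(
      region = config$region, movie = movie, track_id_cells = ids,
      minute = t,
      center_x_cells = rowMeans(Xt), center_y_cells = rowMeans(Yt),
      vx_coords_cells = vx_strings, CRISPR = genotype,
      apical_area_pixels = areas[, t],
      medial_actin = medial_actin[, t],
      junctional_actin = junctional_actin[, t],
      medial_Ncadherin = medial_Ncadherin[, t],
      junctional_Ncadherin = junctional_Ncadherin[, t],
      medial_memBFP = medial_memBFP[, t],
      junctional_memBFP = junctional_memBFP[, t]
    )
  }
  cell_surfaces <- dplyr::bind_rows(cell_rows) |>
    dplyr::left_join(ncounts, by = c("minute", "track_id_cells")) |>
    dplyr::arrange(.data$track_id_cells, .data$minute)
  cell_surfaces <- cell_surfaces[
    , intersect(names(cell_surfaces_cols), names(cell_surfaces))]

  # --- junction table ---
  junctions <- build_junction_table(config, mesh, base_adj, events, positions,
                                    labels, movie,
                                    junctional_actin, junctional_Ncadherin)

  truth <- list(
    genotype = labels, regime = setNames(regime, ids),
    coupling = config$coupling, areas = areas, z_area = z_area,
    t1_events = if (length(events) == 0) {
      tibble::tibble(cell_a = character(), cell_b = character(),
                     cell_c = character(), cell_d = character(),
                     frame = integer())
    } else {
      dplyr::bind_rows(lapply(events, function(e) tibble::tibble(
        cell_a = e$ab[1], cell_b = e$ab[2],
        cell_c = e$cd[1], cell_d = e$cd[2], frame = e$frame)))
    },
    channel_means = list(
      medial_actin = medial_actin, junctional_actin = junctional_actin,
      medial_Ncadherin = medial_Ncadherin,
      junctional_Ncadherin = junctional_Ncadherin,
      medial_memBFP = medial_memBFP, junctional_memBFP = junctional_memBFP
    )
  )
  list(
    dataset = tracking_dataset(cell_surfaces = cell_surfaces,
                               junctions = junctions),
    adjacency = adjacency, truth = truth, positions = positions,
    mesh = mesh, config = config, movie = movie
  )
}

# pick edges for scripted T1 events: interior edges whose two end-vertices
# each border a third cell (the gaining pair), disjoint across events
script_t1_events <- function(config, mesh, base_adj) {
  if (length(config$t1_frames) == 0) return(list())
  idx <- do.call(rbind, mesh$cells)
  ids <- mesh$cell_ids
  # map vertex -> owning cells
  v_owner <- split(rep(seq_len(nrow(idx)), 6), as.vector(idx))
  events <- list()
  used <- character()
  for (f in sort(config$t1_frames)) {
    found <- FALSE
    for (k in seq_len(nrow(base_adj))) {
      a <- base_adj$cell_a[k]; b <- base_adj$cell_b[k]
      ai <- match(a, ids); bi <- match(b, ids)
      c1 <- setdiff(v_owner[[as.character(base_adj$v1[k])]], c(ai, bi))
      c2 <- setdiff(v_owner[[as.character(base_adj$v2[k])]], c(ai, bi))
      if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
      quad <- c(a, b, ids[c1], ids[c2])
      if (any(quad %in% used)) next
      if (f < 2 || f > config$n_frames - 4) next
      events[[length(events) + 1]] <- list(
        frame = f, ab = c(a, b), cd = sort(ids[c(c1, c2)])
      )
      used <- c(used, quad)
      found <- TRUE
      break
    }
    if (!found) {
      abort_constrictr(sprintf("no eligible edge for a T1 event at frame %d", f),
                       "constrictr_config_error")
    }
  }
  events
}

build_junction_table <- function(config, mesh, base_adj, events, positions,
                                 labels, movie, junctional_actin,
                                 junctional_Ncadherin) {
  n_f <- config$n_frames
  ids <- mesh$cell_ids
  s <- config$microns_per_pixel
  rows <- vector("list", nrow(base_adj) + length(events))
  # per-junction static z displacement
  dz_all <- stats::runif(nrow(base_adj) + length(events), 0, config$z_amp_micron)
  make_rows <- function(track_id, a, b, frames, v1x, v1y, v2x, v2y, dz) {
    ai <- match(a, ids); bi <- match(b, ids)
    actin <- (junctional_actin[ai, frames] + junctional_actin[bi, frames]) / 2
    ncad <- (junctional_Ncadherin[ai, frames] + junctional_Ncadherin[bi, frames]) / 2
    len_px <- sqrt((v2x - v1x)^2 + (v2y - v1y)^2)
    tibble::tibble(
      region = config$region, movie = movie,
      track_id_junctions = track_id,
      CRISPR = classify_junction(labels[[a]], labels[[b]]),
      minute = frames,
      vx_1_x = v1x, vx_1_y = v1y, vx_2_x = v2x, vx_2_y = v2y,
      actin = actin, Ncadherin = ncad,
      length_px = len_px, length_micron = len_px * s,
      delta_z_micron = dz,
      length_corrected = sqrt((len_px * s)^2 + dz^2),
      orientation = junction_orientation(v1x, v1y, v2x, v2y, 90)
    )
  }
  lost_until <- setNames(rep(n_f + 1L, nrow(base_adj)), paste(base_adj$cell_a, base_adj$cell_b))
  for (e in events) {
    key1 <- paste(e$ab[1], e$ab[2]); key2 <- paste(e$ab[2], e$ab[1])
    lost_until[names(lost_until) %in% c(key1, key2)] <- e$frame
  }
  for (k in seq_len(nrow(base_adj))) {
    a <- base_adj$cell_a[k]; b <- base_adj$cell_b[k]
    last_f <- lost_until[[paste(a, b)]] - 1L
    frames <- seq_len(min(last_f, n_f))
    rows[[k]] <- make_rows(
      sprintf("j_%s_%s", a, b), a, b, frames,
      positions[frames, base_adj$v1[k], 1], positions[frames, base_adj$v1[k], 2],
      positions[frames, base_adj$v2[k], 1], positions[frames, base_adj$v2[k], 2],
      dz_all[k]
    )
  }
  # gained junctions from scripted events: expand orthogonally from the
  # collapsed edge midpoint toward the gaining cells
  for (i in seq_along(events)) {
    e <- events[[i]]
    k <- which((base_adj$cell_a == e$ab[1] & base_adj$cell_b == e$ab[2]) |
                 (base_adj$cell_a == e$ab[2] & base_adj$cell_b == e$ab[1]))[1]
    frames <- e$frame:n_f
    mx <- (positions[frames, base_adj$v1[k], 1] +
             positions[frames, base_adj$v2[k], 1]) / 2
    my <- (positions[frames, base_adj$v1[k], 2] +
             positions[frames, base_adj$v2[k], 2]) / 2
    ci <- match(e$cd[1], ids); di <- match(e$cd[2], ids)
    idx <- do.call(rbind, mesh$cells)
    ccx <- mean(positions[e$frame, idx[ci, ], 1])
    ccy <- mean(positions[e$frame, idx[ci, ], 2])
    dcx <- mean(positions[e$frame, idx[di, ], 1])
    dcy <- mean(positions[e$frame, idx[di, ], 2])
    u <- c(dcx - ccx, dcy - ccy)
    u <- u / sqrt(sum(u^2))
    h <- pmin(2, 0.5 * (frames - e$frame + 1))
    rows[[nrow(base_adj) + i]] <- make_rows(
      sprintf("j_%s_%s", e$cd[1], e$cd[2]), e$cd[1], e$cd[2], frames,
      mx - h * u[1], my - h * u[2], mx + h * u[1], my + h * u[2],
      dz_all[nrow(base_adj) + i]
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$track_id_junctions, .data$minute)
}
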