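# Nucleus-level spot simulator: chromosome-territory placement inside a
# unit-disk nucleus (a 2-D microscopy projection), with detection noise,
# signal splitting and uniform background spots.

#' Simulation configuration
#'
#' @param n_cells Cells simulated per hybridization (default 20, the minimum
#'   number of interphase nuclei scored per chromosome).
#' @param nucleus_radius Nucleus radius; the coordinate unit (fixed 1.0 by
#'   default).
#' @param territory_sd Dispersion of a chromosome copy's signals around its
#'   territory center, in nucleus radii. `Inf` switches to a calibration
#'   mode in which every signal is placed i.i.d. uniformly in the disk with
#'   no resolution constraint (used to study chance colocalization).
#' @param fusion_distance True-fusion placement bound and the default spot
#'   extraction radius.
#' @param p_detect Probability a true signal yields a spot.
#' @param p_split Probability a detected signal yields a second spot within
#'   `fusion_distance` of the first (split signals re-merge at extraction).
#' @param background_rate Expected spurious spots per cell per color
#'   (Poisson), placed uniformly.
#' @param seed Integer RNG seed.
#' @param min_separation Minimum distance enforced between spots of
#'   different signal groups in territory mode, so that distinct noise-free
#'   signals are never scored as juxtaposed by chance; defaults to
#'   `2 * fusion_distance`.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_cells = 20L, nucleus_radius = 1.0,
                              territory_sd = 0.06, fusion_distance = 0.05,
                              p_detect = 1.0, p_split = 0.0,
                              background_rate = 0.0, seed = 1L,
                              min_separation = NULL) {
  stopifnot(
    n_cells >= 1L,
    p_detect >= 0, p_detect <= 1,
    p_split >= 0, p_split <= 1,
    background_rate >= 0,
    fusion_distance > 0, fusion_distance < nucleus_radius,
    territory_sd > 0
  )
  structure(
    list(n_cells = as.integer(n_cells), nucleus_radius = nucleus_radius,
         territory_sd = territory_sd, fusion_distance = fusion_distance,
         p_detect = p_detect, p_split = p_split,
         background_rate = background_rate, seed = as.integer(seed),
         min_separation = min_separation %||% (2 * fusion_distance)),
    class = "sim_config"
  )
}

#' Derive a per-hybridization RNG seed
#'
#' Deterministic polynomial hash of the hybridization id combined with the
#' master seed, so per-hybridization streams are reproducible independently
#' of iteration order.
#'
#' @param seed Master integer seed.
#' @param hyb_id Hybridization identifier.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, hyb_id) {
  h <- 0
  for (ch in utf8ToInt(hyb_id)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 2146 + (h %% 2146) + h)
}

runif_disk <- function(n, radius = 1.0) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

# one point ~ N(center, sd^2 I) conditioned on lying inside the disk
rnorm_in_disk <- function(center, sd, radius) {
  for (i in 1:50) {
    p <- center + stats::rnorm(2, sd = sd)
    if (sum(p^2) <= radius^2) return(p)
  }
  center / max(1, sqrt(sum(center^2)) / radius)
}

# uniform point in the ball of given radius around a center, kept inside the
# nucleus
runif_near <- function(center, radius, nucleus_radius) {
  for (i in 1:50) {
    p <- center + runif_disk(1, radius)[1, ]
    if (sum(p^2) <= nucleus_radius^2) return(p)
  }
  center
}

min_cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

# Place all true spots of one cell. Returns data.frame(color, x, y).
# In territory mode, spots of different signal groups are kept at least
# min_separation apart (finite optical resolution: distinct loci resolve as
# distinct spots); fused groups are placed within 0.9 * fusion_distance.
place_cell <- function(layout, config) {
  R <- config$nucleus_radius
  uniform_mode <- is.infinite(config$territory_sd)
  colors <- character(); coords <- matrix(numeric(0), ncol = 2)
  group_id <- integer(); gid <- 0L

  place_group <- function(base, g) {
    k <- length(g$colors)
    pts <- matrix(base, nrow = 1)
    if (k > 1L) {
      for (j in 2:k) {
        pts <- rbind(pts, runif_near(base, 0.45 * config$fusion_distance, R))
      }
    }
    pts
  }

  if (uniform_mode) {
    for (terr in layout) {
      for (g in terr$groups) {
        gid <- gid + 1L
        base <- runif_disk(1, R)[1, ]
        pts <- place_group(base, g)
        coords <- rbind(coords, pts)
        colors <- c(colors, g$colors)
        group_id <- c(group_id, rep(gid, length(g$colors)))
      }
    }
  } else {
    sep <- config$min_separation
    for (terr in layout) {
      ok <- FALSE
      for (attempt in 1:300) {
        center <- runif_disk(1, R)[1, ]
        t_coords <- matrix(numeric(0), ncol = 2)
        t_colors <- character(); t_gid <- integer()
        good <- TRUE
        for (gi in seq_along(terr$groups)) {
          g <- terr$groups[[gi]]
          base <- rnorm_in_disk(center, config$territory_sd, R)
          pts <- place_group(base, g)
          if (nrow(t_coords) && min_cross_dist(pts, t_coords) <= sep) {
            good <- FALSE; break
          }
          t_coords <- rbind(t_coords, pts)
          t_colors <- c(t_colors, g$colors)
          t_gid <- c(t_gid, rep(gi, length(g$colors)))
        }
        if (good && nrow(coords) &&
            min_cross_dist(t_coords, coords) <= sep) {
          good <- FALSE
        }
        if (good) {
          coords <- rbind(coords, t_coords)
          colors <- c(colors, t_colors)
          group_id <- c(group_id, gid + t_gid)
          gid <- gid + length(terr$groups)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        # nucleus too crowded to honor the separation; place unconstrained
        for (g in terr$groups) {
          gid <- gid + 1L
          base <- rnorm_in_disk(runif_disk(1, R)[1, ], config$territory_sd, R)
          pts <- place_group(base, g)
          coords <- rbind(coords, pts)
          colors <- c(colors, g$colors)
          group_id <- c(group_id, rep(gid, length(g$colors)))
        }
      }
    }
  }

  df <- data.frame(color = colors,
                   x = coords[, 1] %||% numeric(0),
                   y = coords[, 2] %||% numeric(0),
                   stringsAsFactors = FALSE)

  # detection noise
  if (config$p_detect < 1 && nrow(df)) {
    df <- df[stats::runif(nrow(df)) <= config$p_detect, , drop = FALSE]
  }
  # split signals: duplicate spot within the fusion distance of the parent
  if (config$p_split > 0 && nrow(df)) {
    split_idx <- which(stats::runif(nrow(df)) <= config$p_split)
    for (i in split_idx) {
      p <- runif_near(c(df$x[i], df$y[i]), 0.9 * config$fusion_distance, R)
      df <- rbind(df, data.frame(color = df$color[i], x = p[1], y = p[2],
                                 stringsAsFactors = FALSE))
    }
  }
  # uniform background spots
  if (config$background_rate > 0) {
    for (col in ICP_COLORS) {
      k <- stats::rpois(1, config$background_rate)
      if (k > 0) {
        pts <- runif_disk(k, R)
        df <- rbind(df, data.frame(color = col, x = pts[, 1], y = pts[, 2],
                                   stringsAsFactors = FALSE))
      }
    }
  }
  df
}

normalize_populations <- function(populations) {
  if (inherits(populations, "karyotype_spec") || is.character(populations)) {
    populations <- list(list(karyotype = populations, fraction = 1))
  }
  pops <- lapply(populations, function(p) {
    spec <- p$spec %||% p$karyotype
    if (is.character(spec)) spec <- parse_karyotype_spec(spec)
    list(spec = spec, fraction = p$fraction %||% 1)
  })
  if (!length(pops)) stop("empty population list")
  fr <- vapply(pops, function(p) p$fraction, numeric(1))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("population fractions must be non-negative and sum to 1 (got ",
         paste(signif(fr, 4), collapse = ", "), ")")
  }
  pops
}

#' Simulate per-cell spots for one hybridization
#'
#' Each cell is drawn from one population (multinomial by fraction); the
#' population's noise-free layout places one territory per chromosome copy
#' uniformly in the unit-disk nucleus with isotropic Gaussian scatter of its
#' signals; fused groups stay within the fusion distance; detection noise,
#' signal splitting and background spots are applied per
#' [simulation_config()]. Deterministic given (populations, hybridization,
#' config, seed).
#'
#' @param populations A karyotype string, `karyotype_spec`, or list of
#'   `list(karyotype=, fraction=)` populations with fractions summing to 1.
#' @param hyb An `icp_hybridization`.
#' @param config A [simulation_config()].
#' @return Spot table: data.frame(cell_id, hyb_id, color, x, y) with cell
#'   ids dense in `1:n_cells` (cells may have zero rows under detection
#'   noise).
#' @export
simulate_hybridization <- function(populations, hyb, config = simulation_config()) {
  pops <- normalize_populations(populations)
  if (config$n_cells < 1L) stop("n_cells must be >= 1")
  set.seed(config$seed)
  layouts <- lapply(pops, function(p) expected_signal_layout(p$spec, hyb))
  fr <- vapply(pops, function(p) p$fraction, numeric(1))
  which_pop <- sample.int(length(pops), config$n_cells, replace = TRUE,
                          prob = fr)
  out <- vector("list", config$n_cells)
  for (cell in seq_len(config$n_cells)) {
    df <- place_cell(layouts[[which_pop[cell]]], config)
    if (nrow(df)) {
      df <- cbind(data.frame(cell_id = cell, hyb_id = hyb$id,
                             stringsAsFactors = FALSE), df)
    } else {
      df <- data.frame(cell_id = integer(0), hyb_id = character(0),
                       color = character(0), x = numeric(0), y = numeric(0))
    }
    out[[cell]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a case across a panel
#'
#' One spot table per hybridization; each hybridization gets its own RNG
#' stream via [derive_seed()], so results do not depend on iteration order.
#'
#' @inheritParams simulate_hybridization
#' @param panel An `icp_panel`.
#' @return Named list (hybridization id -> spot table).
#' @export
simulate_case <- function(populations, panel, config = simulation_config()) {
  pops <- normalize_populations(populations)
  res <- lapply(panel$hybridizations, function(hyb) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, hyb$id)
    simulate_hybridization(pops, hyb, cfg)
  })
  names(res) <- names(panel$hybridizations)
  res
}

#' Simulate a full profiling run (Standard panel plus Acrocentric mix)
#'
#' @inheritParams simulate_hybridization
#' @param include_acro Include the Acrocentric hybridization (needed to
#'   detect Robertsonian translocations).
#' @return Named list of spot tables covering `chr1`..`chr22`, `chrXY` and
#'   (by default) `acro`.
#' @export
simulate_icp_case <- function(populations, config = simulation_config(),
                              include_acro = TRUE) {
  tables <- simulate_case(populations, build_standard_panel(), config)
  if (include_acro) {
    tables <- c(tables, simulate_case(populations, build_acrocentric_panel(),
                                      config))
  }
  tables
}

#' Write / read a spot table as TSV
#'
#' Plain tab-separated text with header `cell_id, hyb_id, color, x, y`.
#'
#' @param spots Spot table data frame.
#' @param path File path.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "hyb_id", "color", "x", "y")
  if (!all(need %in% names(df))) {
    stop("spot table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}
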