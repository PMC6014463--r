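# Workbench: packaged validation fixtures, karyotype resolution for
# simulation scenarios, the end-to-end pipeline convenience wrapper, and
# the functions behind the command-line interface.

fixtures_dir <- function() {
  system.file("extdata", package = "icprofiler")
}

read_fixture_tsv <- function(path) {
  if (!file.exists(path)) stop("missing fixture file: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("empty fixture file: ", path)
  df
}

#' Load the packaged validation tables
#'
#' Tables 1-3 carry one row per specimen; table 4 one row per printed
#' result class, expanded here to per-specimen records (specimens within a
#' class are assigned the female variant first, following the printed
#' per-sex counts).
#'
#' @param dir Fixture directory; defaults to the files shipped with the
#'   package.
#' @return List with elements `table1`..`table4` (as shipped), and
#'   `records`: one data frame of all specimen-level records with columns
#'   specimen_id, source_table, cytogenetic_result, icp_result, concordant.
#' @export
load_validation_tables <- function(dir = fixtures_dir()) {
  t1 <- read_fixture_tsv(file.path(dir, "table1.tsv"))
  t2 <- read_fixture_tsv(file.path(dir, "table2.tsv"))
  t3 <- read_fixture_tsv(file.path(dir, "table3.tsv"))
  t4 <- read_fixture_tsv(file.path(dir, "table4.tsv"))

  expand4 <- do.call(rbind, lapply(seq_len(nrow(t4)), function(i) {
    rng <- as.integer(strsplit(t4$specimens[i], "-", fixed = TRUE)[[1]])
    ids <- if (length(rng) == 1L) rng else seq(rng[1], rng[2])
    n_f <- t4$n_female[i]
    res <- t4$icp_result[i]
    sex_hint <- c(rep("female", n_f), rep("male", length(ids) - n_f))
    data.frame(specimen_id = ids, source_table = "T4",
               cytogenetic_result = NA_character_, icp_result = res,
               concordant = NA_character_, sex_hint = sex_hint,
               stringsAsFactors = FALSE)
  }))

  rec <- function(df, tab) {
    data.frame(specimen_id = df$specimen_id, source_table = tab,
               cytogenetic_result = df$cytogenetic_result,
               icp_result = df$icp_result, concordant = df$concordant,
               sex_hint = NA_character_, stringsAsFactors = FALSE)
  }
  records <- rbind(rec(t1, "T1"), rec(t2, "T2"), rec(t3, "T3"), expand4)
  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
       records = records)
}

resolve_sex_for <- function(spec, prefer = c("female", "male")) {
  prefer <- match.arg(prefer)
  alts <- spec$sex_alternatives
  alts <- alts[!is.na(alts)]
  alts <- alts[nzchar(alts)]
  default_female <- strrep("X", max(2L, spec$base_ploidy))
  if (!length(alts)) {
    # sex unstated (descriptive shorthand or an empty printed alternative):
    # assume the all-X complement matching the ploidy
    return(strsplit(default_female, "")[[1]])
  }
  has_y <- grepl("Y", alts)
  pick <- if (prefer == "female" && any(!has_y)) alts[!has_y][1]
    else if (prefer == "male" && any(has_y)) alts[has_y][1]
    else alts[1]
  strsplit(pick, "")[[1]]
}

#' Resolve a result string into simulable populations
#'
#' Turns any supported result string (structured or descriptive, including
#' "XX or XY" alternatives and mosaic "/" calls) into a concrete list of
#' `list(spec, fraction)` populations for the simulator. Alternative sex
#' complements are resolved per `prefer`; a printed chromosome count
#' inconsistent with the listed events is replaced by the event-implied
#' count; mosaic calls get fractions 0.65/0.35 (majority first) unless the
#' string states a percentage.
#'
#' @param text Result string.
#' @param prefer Preferred sex variant when the string allows both.
#' @return List of populations, each `list(spec = karyotype_spec,
#'   fraction = numeric)`.
#' @export
resolve_icp_to_populations <- function(text, prefer = "female") {
  call <- parse_icp_string(text, strict = FALSE)
  pops <- list()
  for (spec in call$populations) {
    sex <- resolve_sex_for(spec, prefer)
    sp <- new_karyotype_spec(
      base_ploidy = spec$base_ploidy, sex = sex, gains = spec$gains,
      losses = spec$losses, events = spec$events
    )
    sp$count <- implied_count(sp)
    frac <- spec$annotations$mosaic_fraction %||%
      (if (!is.null(spec$annotations$cells)) spec$annotations$cells / 20
       else NA_real_)
    mosaic_note <- isTRUE(spec$annotations$mosaic) ||
      !is.null(spec$annotations$cells) || !is.na(frac)
    pops <- c(pops, list(list(spec = sp, fraction = frac,
                              mosaic = mosaic_note)))
  }
  if (length(pops) == 1L) {
    p <- pops[[1]]
    if (p$mosaic) {
      # descriptive "(mosaic)" shorthand: pair with a normal diploid clone
      frac <- p$fraction
      if (is.na(frac)) frac <- 0.35
      normal <- new_karyotype_spec(base_ploidy = 2L, sex = c("X", "X"))
      normal$count <- 46L
      return(list(list(spec = p$spec, fraction = frac),
                  list(spec = normal, fraction = 1 - frac)))
    }
    return(list(list(spec = p$spec, fraction = 1)))
  }
  # explicit "/" populations: majority listed first
  fr <- vapply(pops, function(p)
    if (is.na(p$fraction)) NA_real_ else p$fraction, numeric(1))
  if (all(is.na(fr))) fr <- c(0.65, rep(0.35 / (length(pops) - 1),
                                        length(pops) - 1))
  lapply(seq_along(pops), function(i)
    list(spec = pops[[i]]$spec, fraction = fr[i]))
}

#' Simulate and call one case end to end
#'
#' Convenience wrapper: resolves the karyotype, simulates the Standard
#' panel plus the Acrocentric mix, extracts, calls and assembles.
#'
#' @param karyotype Result string, `karyotype_spec`, or population list.
#' @param sim_config A [simulation_config()].
#' @param call_config A [caller_config()]; its fusion radius defaults to
#'   the simulator's fusion distance.
#' @return An `icp_genome_call`.
#' @export
run_icp_case <- function(karyotype, sim_config = simulation_config(),
                         call_config = NULL) {
  pops <- if (is.character(karyotype)) {
    resolve_icp_to_populations(karyotype)
  } else karyotype
  if (is.null(call_config)) {
    call_config <- caller_config(fusion_radius = sim_config$fusion_distance)
  }
  tables <- simulate_icp_case(pops, sim_config)
  call_genome(tables, call_config, n_cells = sim_config$n_cells)
}

# ---------------------------------------------------------------------------
# CLI backing functions (thin wrappers used by exec/icp)

read_scenario <- function(scenario) {
  if (is.character(scenario)) {
    if (!file.exists(scenario)) stop("scenario file not found: ", scenario)
    scenario <- jsonlite::read_json(scenario, simplifyVector = FALSE)
  }
  scenario
}

#' Simulate a scenario to spot-table files
#'
#' Reads a scenario (JSON path or list) with either a `karyotype` string or
#' a `populations` list of `{karyotype, fraction}`, plus an optional
#' `config` block of [simulation_config()] fields, writes one TSV spot
#' table per hybridization and a manifest recording files, per-
#' hybridization seeds and the full configuration.
#'
#' @param scenario Scenario JSON path or equivalent list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master seed overriding the scenario's.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
cli_simulate <- function(scenario, out_dir, seed = NULL) {
  sc <- read_scenario(scenario)
  cfg_args <- sc$config %||% list()
  if (!is.null(seed)) cfg_args$seed <- seed
  config <- do.call(simulation_config, cfg_args)
  pops <- if (!is.null(sc$populations)) {
    lapply(sc$populations, function(p)
      list(spec = parse_karyotype_spec(p$karyotype, strict = FALSE),
           fraction = p$fraction %||% 1))
  } else if (!is.null(sc$karyotype)) {
    resolve_icp_to_populations(sc$karyotype)
  } else {
    stop("scenario must provide 'karyotype' or 'populations'")
  }
  pops <- normalize_populations(pops)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- simulate_icp_case(pops, config)
  files <- character(); seeds <- integer()
  for (id in names(tables)) {
    f <- file.path(out_dir, paste0(id, ".tsv"))
    write_spot_table(tables[[id]], f)
    files[id] <- basename(f)
    seeds[id] <- derive_seed(config$seed, id)
  }
  manifest <- list(
    populations = lapply(pops, function(p)
      list(karyotype = render_karyotype(p$spec), fraction = p$fraction)),
    config = unclass(config), seed = config$seed,
    files = as.list(files), hybridization_seeds = as.list(seeds)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Call a genome from spot-table files
#'
#' @param inputs Directory of per-hybridization `*.tsv` spot tables, a
#'   character vector of file paths, or a combined spot-table data frame.
#' @param out Optional path for the JSON report.
#' @param config A [caller_config()].
#' @param n_cells Cells analyzed per hybridization (defaults to the
#'   largest cell id per table).
#' @param quiet Suppress printing the icp string to stdout.
#' @return The `icp_genome_call`, invisibly.
#' @export
cli_call <- function(inputs, out = NULL, config = caller_config(),
                     n_cells = NULL, quiet = FALSE) {
  if (is.data.frame(inputs)) {
    spots <- inputs
  } else {
    paths <- inputs
    if (length(paths) == 1L && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
    }
    paths <- paths[!grepl("manifest", paths)]
    if (!length(paths)) stop("no spot-table files found")
    spots <- do.call(rbind, lapply(paths, read_spot_table))
  }
  if (!nrow(spots)) stop("no parseable cells in input")
  call <- call_genome(spots, config, n_cells = n_cells)
  if (!quiet) cat(call$icp_string, "\n", sep = "")
  if (!is.null(out)) genome_call_report(call, out, config = config)
  invisible(call)
}

#' Validate the packaged result tables
#'
#' Classifies every fixture record as normal or abnormal, reports
#' per-table counts and abnormality rates (rounded to the nearest percent,
#' matching the headline convention), and optionally re-simulates every
#' stage-2 laboratory-1 specimen noise-free for an end-to-end round-trip
#' concordance check.
#'
#' @param dir Fixture directory (defaults to the packaged tables).
#' @param round_trip Run the laboratory-1 simulate-and-recall check.
#' @param sim_config Simulation settings for the round trip.
#' @return List with `summary` (per-table data frame: n, n_abnormal,
#'   abnormality_rate_pct) and, when requested, `round_trip` (per-specimen
#'   data frame with emitted string and match flag) and
#'   `round_trip_concordance`.
#' @export
cli_validate_tables <- function(dir = fixtures_dir(), round_trip = TRUE,
                                sim_config = simulation_config()) {
  tabs <- load_validation_tables(dir)
  rec <- tabs$records
  rec$abnormal <- vapply(rec$icp_result, classify_abnormal, logical(1))
  summary <- do.call(rbind, lapply(split(rec, rec$source_table), function(d) {
    data.frame(table = d$source_table[1], n = nrow(d),
               n_abnormal = sum(d$abnormal),
               abnormality_rate_pct = round(100 * mean(d$abnormal)),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  out <- list(summary = summary, records = rec)
  if (round_trip) {
    t3 <- tabs$table3
    res <- lapply(seq_len(nrow(t3)), function(i) {
      cfg <- sim_config
      cfg$seed <- derive_seed(sim_config$seed, paste0("t3-", t3$specimen_id[i]))
      call <- run_icp_case(t3$icp_result[i], cfg)
      data.frame(specimen_id = t3$specimen_id[i],
                 expected = t3$icp_result[i], emitted = call$icp_string,
                 match = same_karyotype_class(call$icp_string,
                                              t3$icp_result[i]),
                 stringsAsFactors = FALSE)
    })
    rt <- do.call(rbind, res)
    out$round_trip <- rt
    out$round_trip_concordance <- mean(rt$match)
  }
  out
}
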