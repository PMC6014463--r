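# Genome-wide assembly: ploidy and sex inference, Robertsonian detection,
# translocation pairing, mosaic/admixture populations, and the final
# "icp." karyotype string.

ploidy_label <- function(baseline) {
  switch(as.character(baseline), "2" = "DIPLOID", "3" = "TRIPLOID",
         "4" = "TETRAPLOID", "OTHER")
}

#' Infer genome ploidy from autosomal calls
#'
#' The baseline copy number is the modal primary count across autosomal
#' pericentromeric targets; 2/3/4 map to DIPLOID/TRIPLOID/TETRAPLOID.
#' Per-chromosome gains and losses are interpreted relative to this
#' baseline downstream.
#'
#' @param cen_primaries Named integer vector of autosomal CEN primary
#'   copy numbers (names are chromosomes), or a list of
#'   `icp_chromosome_call`.
#' @return List with `baseline`, `ploidy` label and `flags`.
#' @export
infer_ploidy <- function(cen_primaries) {
  if (is.list(cen_primaries) && !is.null(cen_primaries[[1]]$target_calls)) {
    cen_primaries <- vapply(cen_primaries, function(cc)
      cc$target_calls$CEN$primary_copy_number, integer(1))
  }
  cen_primaries <- cen_primaries[!is.na(cen_primaries)]
  if (length(cen_primaries) < 2L) {
    stop("ploidy inference requires calls for at least 2 autosomes")
  }
  flags <- character()
  if (length(cen_primaries) < 20L) {
    flags <- c(flags, "few_autosomes_for_ploidy")
  }
  baseline <- modal_count(cen_primaries)
  list(baseline = as.integer(baseline), ploidy = ploidy_label(baseline),
       flags = flags)
}

#' Infer the sex-chromosome complement from the joint X/Y hybridization
#'
#' X copies equal the X p-subtelomere (GREEN) primary count and Y copies
#' the Y p-subtelomere (AQUA) primary count; the shared pericentromeric
#' (YELLOW) count is checked against X+Y. A q-subtelomere (RED, shared by
#' Xq and Yq) deficit is attributed to the X chromosome when no Y is
#' present, otherwise flagged as ambiguous.
#'
#' @param xy_target_calls Named list of `icp_target_call` with entries
#'   `X_PTER`, `Y_PTER`, `CEN`, `QTER`.
#' @param displaced Optional named displacement evidence (`q` entry for the
#'   shared q-subtelomere color).
#' @return List with `sex` (character vector of "X"/"Y"), `events` (X
#'   terminal events, for translocation assembly) and `flags`.
#' @export
infer_sex <- function(xy_target_calls, displaced = list()) {
  x_n <- xy_target_calls$X_PTER$primary_copy_number
  y_n <- xy_target_calls$Y_PTER$primary_copy_number
  cen <- xy_target_calls$CEN$primary_copy_number
  qter <- xy_target_calls$QTER$primary_copy_number
  flags <- character(); events <- list()
  if (cen != x_n + y_n) {
    flags <- c(flags, sprintf("xy_cen_count_%d_vs_XY_%d", cen, x_n + y_n))
  }
  qd <- (x_n + y_n) - qter
  if (qd > 0) {
    if (y_n == 0L) {
      events <- c(events, lapply(seq_len(qd), function(i)
        list(type = "TERMINAL_DEL", chromosome = "X", arm = "q")))
    } else {
      flags <- c(flags, "sex_qter_deletion_ambiguous_X_vs_Y")
    }
  } else if (qd < 0) {
    if (y_n == 0L) {
      events <- c(events, lapply(seq_len(-qd), function(i)
        list(type = "EXTRA_TERMINAL", chromosome = "X", arm = "q",
             displaced = TRUE)))
    } else {
      flags <- c(flags, "sex_qter_gain_ambiguous_X_vs_Y")
    }
  } else if (!is.null(displaced$q) && isTRUE(displaced$q$abnormal)) {
    if (y_n == 0L) {
      events <- c(events, list(list(type = "DISPLACED", chromosome = "X",
                                    arm = "q")))
    } else {
      flags <- c(flags, "sex_qter_displacement_ambiguous_X_vs_Y")
    }
  }
  list(sex = c(rep("X", x_n), rep("Y", y_n)), events = events, flags = flags)
}

#' Detect Robertsonian translocations from the acrocentric mix
#'
#' Each abnormal pairwise pericentromeric fusion becomes a Robertsonian
#' derivative der(a;b)(q10;q10); it is unbalanced (translocation trisomy,
#' `extra_copy_of` set) when exactly one participant's total count exceeds
#' the baseline, balanced when both totals equal it. A color participating
#' in more than one abnormal fusion (a fusion among more than two colors)
#' is flagged and not auto-resolved.
#'
#' @param acro_patterns List of `icp_cell_pattern` from the acrocentric
#'   hybridization.
#' @param config A [caller_config()].
#' @param baseline Genome baseline copy number.
#' @param color_map Named chromosome-by-color map (default
#'   [acro_color_map()]).
#' @return List with `events` (ROBERTSONIAN `structural_event`s),
#'   `target_calls`, `fusion_calls` and `flags`.
#' @export
detect_robertsonian <- function(acro_patterns, config = caller_config(),
                                baseline = 2L,
                                color_map = acro_color_map()) {
  colors <- names(color_map)
  target_calls <- lapply(stats::setNames(colors, colors), function(col)
    call_copy_number(acro_patterns, col, config))
  pairs <- utils::combn(colors, 2, simplify = FALSE)
  fusion_calls <- lapply(pairs, function(p)
    call_fusion(acro_patterns, p, config))
  abnormal <- Filter(function(fc) fc$abnormal, fusion_calls)
  flags <- character(); events <- list()
  involved <- unlist(lapply(abnormal, function(fc) fc$color_pair))
  complex_colors <- unique(involved[duplicated(involved)])
  if (length(complex_colors)) {
    flags <- c(flags, paste0(
      "complex_acro_fusion_", paste(sort(color_map[complex_colors]),
                                    collapse = "_")))
  }
  for (fc in abnormal) {
    if (any(fc$color_pair %in% complex_colors)) next
    chroms <- sort(as.character(color_map[fc$color_pair]))
    totals <- vapply(fc$color_pair, function(col)
      target_calls[[col]]$primary_copy_number, integer(1))
    over <- as.character(color_map[fc$color_pair])[totals > baseline]
    extra <- NULL; balanced <- TRUE
    if (length(over) == 1L) {
      extra <- over; balanced <- FALSE
    } else if (length(over) == 2L) {
      flags <- c(flags, paste0("robertsonian_both_gained_",
                               paste(chroms, collapse = "_")))
    } else if (any(totals < baseline)) {
      flags <- c(flags, paste0("robertsonian_participant_lost_",
                               paste(chroms, collapse = "_")))
    }
    events <- c(events, list(structural_event(
      "ROBERTSONIAN", chroms, bands = c("q10", "q10"), balanced = balanced,
      extra_copy_of = extra
    )))
  }
  list(events = events, target_calls = target_calls,
       fusion_calls = fusion_calls, flags = flags)
}

#' Pair terminal gain/loss and displacement evidence into translocations
#'
#' A terminal loss on one chromosome plus an extra (displaced) terminal on
#' another pairs into an unbalanced derivative der(B)t(A;B) with "?"
#' breakpoints; two displaced terminals with normal counts pair into a
#' balanced reciprocal translocation; unpaired losses remain terminal
#' deletions and unpaired gains are flagged. Pairing is greedy in
#' ascending chromosome order (the fewest-event assembly); when several
#' pairings are possible the ambiguity is reported as a flag, not an
#' error.
#'
#' @param events Flat list of per-chromosome evidence records with fields
#'   `type` ("TERMINAL_DEL", "EXTRA_TERMINAL", "DISPLACED"), `chromosome`
#'   and `arm`.
#' @return List with `events` (list of `structural_event`) and `flags`.
#' @export
pair_translocations <- function(events) {
  sel <- function(type) {
    ev <- Filter(function(e) e$type == type, events)
    ev[order(vapply(ev, function(e) chrom_rank(e$chromosome), numeric(1)))]
  }
  dels <- sel("TERMINAL_DEL")
  extras <- sel("EXTRA_TERMINAL")
  disps <- sel("DISPLACED")
  out <- list(); flags <- character()
  n_pair <- min(length(dels), length(extras))
  if (n_pair >= 1L && (length(dels) > 1L || length(extras) > 1L)) {
    flags <- c(flags, "ambiguous_translocation_pairing")
  }
  for (i in seq_len(n_pair)) {
    a <- extras[[i]]; b <- dels[[i]]
    chroms <- c(a$chromosome, b$chromosome)
    arms <- c(a$arm, b$arm)
    ord <- order(chrom_rank(chroms))
    out <- c(out, list(structural_event(
      "UNBALANCED_DER", chroms[ord], arms = arms[ord],
      bands = paste0(arms[ord], "?"), balanced = FALSE,
      der_chromosome = b$chromosome
    )))
  }
  if (length(dels) > n_pair) {
    for (b in dels[(n_pair + 1L):length(dels)]) {
      out <- c(out, list(structural_event(
        "TERMINAL_DELETION", b$chromosome, arms = b$arm,
        bands = paste0(b$arm, "?"), balanced = FALSE
      )))
    }
  }
  if (length(extras) > n_pair) {
    for (a in extras[(n_pair + 1L):length(extras)]) {
      flags <- c(flags, paste0("unplaced_terminal_gain_", a$chromosome,
                               a$arm))
    }
  }
  while (length(disps) >= 2L) {
    a <- disps[[1]]; b <- disps[[2]]
    disps <- disps[-(1:2)]
    chroms <- c(a$chromosome, b$chromosome)
    arms <- c(a$arm, b$arm)
    ord <- order(chrom_rank(chroms))
    out <- c(out, list(structural_event(
      "RECIPROCAL_TRANSLOCATION", chroms[ord], arms = arms[ord],
      bands = paste0(arms[ord], "?"), balanced = TRUE
    )))
  }
  if (length(disps) == 1L) {
    flags <- c(flags, paste0("unpaired_displaced_terminal_",
                             disps[[1]]$chromosome, disps[[1]]$arm))
  }
  list(events = out, flags = flags)
}

#' Detect a male/female cell admixture in the X/Y hybridization
#'
#' Partitions cells into AQUA-positive and AQUA-negative classes; when both
#' classes satisfy the mosaic rule (cell count and fraction thresholds),
#' two populations are reported, without designating which is fetal —
#' maternal-cell contamination and true sex-discordant mosaicism are not
#' computationally distinguishable.
#'
#' @param xy_patterns List of `icp_cell_pattern` from the X/Y
#'   hybridization.
#' @param config A [caller_config()].
#' @return NULL, or a list of two populations `list(sex=, fraction=)`
#'   ordered by descending fraction.
#' @export
detect_mcc <- function(xy_patterns, config = caller_config()) {
  aqua_pos <- vapply(xy_patterns, function(p)
    p$color_counts[["AQUA"]] > 0L, logical(1))
  n <- length(aqua_pos)
  n_pos <- sum(aqua_pos); n_neg <- n - n_pos
  ok <- function(k) k >= config$mosaic_min_cells &&
    k / n >= config$mosaic_min_fraction
  if (!ok(n_pos) || !ok(n_neg)) return(NULL)
  class_sex <- function(sel) {
    x <- modal_count(vapply(xy_patterns[sel], function(p)
      as.integer(p$color_counts[["GREEN"]]), integer(1)))
    y <- modal_count(vapply(xy_patterns[sel], function(p)
      as.integer(p$color_counts[["AQUA"]]), integer(1)))
    c(rep("X", x), rep("Y", y))
  }
  pops <- list(
    list(sex = class_sex(!aqua_pos), fraction = n_neg / n),
    list(sex = class_sex(aqua_pos), fraction = n_pos / n)
  )
  pops[order(-vapply(pops, function(p) p$fraction, numeric(1)))]
}

#' Render a genome call as "icp." nomenclature
#'
#' "icp." + chromosome count + sex complement + events ordered by lowest
#' chromosome involved (structural events before gains/losses), with "?"
#' breakpoints where unknown, mosaic populations joined by "/", and a
#' final "[cpN]" composite suffix carrying the minimum number of cells
#' analyzed per hybridization.
#'
#' @param call An `icp_genome_call`.
#' @return Character string.
#' @export
to_icp_string <- function(call) {
  primary <- call$spec
  if (implied_count(primary) != call$chromosome_count) {
    stop("genome call chromosome count inconsistent with its events")
  }
  parts <- render_karyotype(primary)
  for (pop in call$populations) {
    if (!is.null(pop$spec)) parts <- c(parts, render_karyotype(pop$spec))
  }
  out <- paste0("icp.", paste(parts, collapse = "/"))
  if (length(call$cells_analyzed)) {
    out <- paste0(out, "[cp", min(unlist(call$cells_analyzed)), "]")
  }
  out
}

#' @export
print.icp_genome_call <- function(x, ...) {
  cat("<icp_genome_call> ", x$icp_string, "\n", sep = "")
  cat("  ploidy ", x$ploidy, ", ", x$chromosome_count, " chromosomes, sex ",
      format_sex(x$sex_complement), "\n", sep = "")
  if (length(x$flags)) {
    cat("  flags: ", paste(x$flags, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

# Build the karyotype_spec of a secondary population: the primary spec with
# this ploidy/sex and per-chromosome copy-number adjustments.
secondary_pop_spec <- function(baseline, sex, adjustments = list()) {
  gains <- character(); losses <- character()
  for (adj in adjustments) {
    d <- adj$copy_number - baseline
    if (d > 0) gains <- c(gains, rep(adj$chromosome, d))
    if (d < 0) losses <- c(losses, rep(adj$chromosome, -d))
  }
  sp <- new_karyotype_spec(base_ploidy = baseline, sex = sex, gains = gains,
                           losses = losses, events = list())
  sp$count <- implied_count(sp)
  sp
}

#' Assemble a genome-wide karyotype call from spot tables
#'
#' Runs the full calling pipeline: per-cell extraction, per-target copy
#' number and fusion calls, ploidy baseline, sex complement, Robertsonian
#' detection from the acrocentric mix, translocation pairing from terminal
#' gain/loss/displacement evidence, mosaic and male/female-admixture
#' populations, and the final nomenclature string.
#'
#' @param spot_tables Named list (hybridization id -> spot table) or one
#'   data frame with a `hyb_id` column. Standard-panel ids `chr1..chr22`,
#'   `chrXY` and the acrocentric id `acro` are recognized.
#' @param config A [caller_config()].
#' @param n_cells Cells analyzed per hybridization; defaults to the
#'   largest cell id present per table.
#' @return An `icp_genome_call`.
#' @export
call_genome <- function(spot_tables, config = caller_config(),
                        n_cells = NULL) {
  if (is.data.frame(spot_tables)) {
    spot_tables <- split(spot_tables, spot_tables$hyb_id)
  }
  std_panel <- build_standard_panel()
  flags <- character()
  autosome_ids <- paste0("chr", 1:22)
  present_auto <- intersect(autosome_ids, names(spot_tables))
  if (length(present_auto) < 2L) {
    stop("need spot tables for at least two autosomal hybridizations")
  }

  patterns <- list(); n_by_hyb <- integer()
  for (id in names(spot_tables)) {
    tab <- spot_tables[[id]]
    nc <- n_cells %||% (if (nrow(tab)) max(tab$cell_id) else 0L)
    if (nc == 0L) stop("no parseable cells in hybridization ", id)
    patterns[[id]] <- extract_patterns(tab, config$fusion_radius,
                                       n_cells = nc)
    n_by_hyb[id] <- nc
    if (nc < config$min_cells) {
      flags <- c(flags, paste0("low_cell_count_", id))
    }
  }

  # ---- raw per-hybridization calls -------------------------------------
  raw <- list()
  for (id in present_auto) {
    hyb <- std_panel$hybridizations[[id]]
    tg <- hyb$targets
    pats <- patterns[[id]]
    tcalls <- lapply(stats::setNames(seq_len(nrow(tg)), tg$locus_class),
                     function(i) call_copy_number(pats, tg$color[i], config))
    pair_list <- utils::combn(tg$color, 2, simplify = FALSE)
    fcalls <- lapply(pair_list, function(p) call_fusion(pats, p, config))
    disp <- list()
    cen_color <- tg$color[tg$locus_class == "CEN"]
    for (arm in c("p", "q")) {
      cls <- if (arm == "p") "PTER" else "QTER"
      if (cls %in% tg$locus_class) {
        disp[[arm]] <- displacement_evidence(
          pats, tg$color[tg$locus_class == cls], cen_color, config)
      }
    }
    raw[[id]] <- list(chromosome = sub("^chr", "", id),
                      target_calls = tcalls, fusion_calls = fcalls,
                      displaced = disp)
  }

  # ---- ploidy baseline -------------------------------------------------
  cen_primary <- vapply(raw, function(r)
    r$target_calls$CEN$primary_copy_number, integer(1))
  cen_secondary <- vapply(raw, function(r)
    r$target_calls$CEN$secondary_copy_number, integer(1))
  sec_frac <- vapply(raw, function(r)
    r$target_calls$CEN$secondary_fraction, numeric(1))
  pl <- infer_ploidy(cen_primary)
  baseline <- pl$baseline
  flags <- c(flags, pl$flags)

  # ---- genome-wide mosaic ploidy level ---------------------------------
  # A second copy-number level supported as {baseline, v} (in either
  # primary/secondary orientation) by at least half the autosomes is a
  # mosaic ploidy population, not 22 independent aneuploidies.
  level_candidates <- setdiff(
    unique(c(cen_primary, cen_secondary[!is.na(cen_secondary)])), baseline)
  mosaic_level <- NULL; mosaic_fraction <- NA_real_
  for (v in level_candidates) {
    support <- (cen_primary == baseline & !is.na(cen_secondary) &
                  cen_secondary == v) |
               (cen_primary == v & (is.na(cen_secondary) |
                  cen_secondary == baseline))
    if (sum(support) >= length(present_auto) / 2) {
      vf <- ifelse(cen_primary[support] == baseline,
                   sec_frac[support], 1 - sec_frac[support])
      mosaic_level <- as.integer(v)
      mosaic_fraction <- mean(vf)
      break
    }
  }
  if (!is.null(mosaic_level) && mosaic_fraction > 0.5) {
    # the modal level was in fact the minority across the genome
    tmp <- baseline; baseline <- mosaic_level; mosaic_level <- tmp
    mosaic_fraction <- 1 - mosaic_fraction
    pl$baseline <- baseline
    pl$ploidy <- ploidy_label(baseline)
  }

  # ---- per-chromosome interpretation -----------------------------------
  chromosome_calls <- list()
  evidence <- list()       # terminal / displacement records for pairing
  gains <- character(); losses <- character()
  isolated_mosaic <- list()
  for (id in present_auto) {
    r <- raw[[id]]
    chr_baseline <- baseline
    if (!is.null(mosaic_level)) {
      prim <- r$target_calls$CEN$primary_copy_number
      sec <- r$target_calls$CEN$secondary_copy_number
      levels_ok <- prim %in% c(baseline, mosaic_level) &&
        (is.na(sec) || sec %in% c(baseline, mosaic_level))
      if (levels_ok) chr_baseline <- prim   # explained by the mosaic mixture
    }
    cc <- interpret_chromosome(r$chromosome, r$target_calls, r$fusion_calls,
                               r$displaced, baseline = chr_baseline,
                               config = config)
    chromosome_calls[[id]] <- cc
    for (ev in cc$events) {
      if (ev$type == "GAIN") gains <- c(gains, ev$chromosome)
      else if (ev$type == "LOSS") losses <- c(losses, ev$chromosome)
      else if (ev$type %in% c("TERMINAL_DEL", "EXTRA_TERMINAL", "DISPLACED")) {
        evidence <- c(evidence, list(ev))
      } else if (ev$type == "FUSION") {
        flags <- c(flags, paste0("unexpected_fusion_chr", r$chromosome))
      }
    }
    if (is.null(mosaic_level) && !is.na(cen_secondary[[id]])) {
      isolated_mosaic <- c(isolated_mosaic, list(list(
        chromosome = r$chromosome, copy_number = cen_secondary[[id]],
        fraction = sec_frac[[id]])))
    }
  }

  # ---- sex complement --------------------------------------------------
  sex <- character(); xy_info <- NULL
  sex_pops <- NULL
  if ("chrXY" %in% names(spot_tables)) {
    hyb <- std_panel$hybridizations[["chrXY"]]
    pats <- patterns[["chrXY"]]
    tg <- hyb$targets
    col_of <- function(chr, cls) tg$color[tg$chromosome == chr &
                                            tg$locus_class == cls]
    xy_calls <- list(
      X_PTER = call_copy_number(pats, col_of("X", "PTER"), config),
      Y_PTER = call_copy_number(pats, col_of("Y", "PTER"), config),
      CEN = call_copy_number(pats, "YELLOW", config),
      QTER = call_copy_number(pats, "RED", config)
    )
    disp_xy <- list(q = displacement_evidence(pats, "RED", "YELLOW", config))
    xy_info <- infer_sex(xy_calls, disp_xy)
    sex <- xy_info$sex
    flags <- c(flags, xy_info$flags)
    evidence <- c(evidence, xy_info$events)
    if (is.null(mosaic_level)) {
      sex_pops <- detect_mcc(pats, config)
    }
    xy_info$target_calls <- xy_calls
  } else {
    flags <- c(flags, "no_xy_hybridization")
  }

  # ---- Robertsonian translocations -------------------------------------
  rob_events <- list()
  if ("acro" %in% names(patterns)) {
    rb <- detect_robertsonian(patterns[["acro"]], config, baseline)
    flags <- c(flags, rb$flags)
    rob_events <- rb$events
    for (i in seq_along(rob_events)) {
      ev <- rob_events[[i]]
      if (!is.null(ev$extra_copy_of)) {
        hit <- match(ev$extra_copy_of, gains)
        if (!is.na(hit)) {
          gains <- gains[-hit]   # the gain is the translocated extra copy
        } else {
          flags <- c(flags, paste0("robertsonian_gain_mismatch_",
                                   ev$extra_copy_of))
        }
      }
    }
  }

  # ---- translocation pairing -------------------------------------------
  tr <- pair_translocations(evidence)
  flags <- c(flags, tr$flags)
  struct_events <- c(rob_events, tr$events)

  # ---- populations ------------------------------------------------------
  populations <- list()
  if (!is.null(mosaic_level)) {
    # Resolve each ploidy population's sex complement jointly per cell:
    # the total X+Y signal count separates the two ploidy levels within
    # the X/Y hybridization, immune to which level happened to be modal
    # there.
    x2 <- NA_integer_; y2 <- NA_integer_
    if (!is.null(xy_info)) {
      pats <- patterns[["chrXY"]]
      tot <- vapply(pats, function(p)
        as.integer(p$color_counts[["GREEN"]] + p$color_counts[["AQUA"]]),
        integer(1))
      tt <- sort(table(tot), decreasing = TRUE)
      if (length(tt) >= 2L) {
        lv <- as.integer(names(tt)[1:2])
        hi <- max(lv); lo <- min(lv)
        base_tot <- if (baseline > mosaic_level) hi else lo
        sex_of <- function(sel) {
          x <- modal_count(vapply(pats[sel], function(p)
            as.integer(p$color_counts[["GREEN"]]), integer(1)))
          y <- modal_count(vapply(pats[sel], function(p)
            as.integer(p$color_counts[["AQUA"]]), integer(1)))
          c(rep("X", x), rep("Y", y))
        }
        sex <- sex_of(tot == base_tot)
        s2 <- sex_of(tot == setdiff(c(hi, lo), base_tot))
        x2 <- sum(s2 == "X"); y2 <- sum(s2 == "Y")
      }
    }
    scale_sex <- function(n, got) {
      if (!is.na(got)) got else as.integer(round(n * mosaic_level / baseline))
    }
    x2 <- scale_sex(sum(sex == "X"), x2)
    y2 <- scale_sex(sum(sex == "Y"), y2)
    sp2 <- secondary_pop_spec(mosaic_level,
                              c(rep("X", x2), rep("Y", y2)))
    populations <- list(list(spec = sp2, fraction = mosaic_fraction,
                             kind = "mosaic_ploidy"))
  } else {
    adj <- isolated_mosaic
    pop_sex <- sex; pop_frac <- numeric(0); kind <- "mosaic"
    if (!is.null(sex_pops)) {
      pop_sex <- sex_pops[[2]]$sex
      pop_frac <- sex_pops[[2]]$fraction
      kind <- "sex_discordant"
      if (!identical(format_sex(sex_pops[[1]]$sex),
                     format_sex(sex_pops[[2]]$sex))) {
        flags <- c(flags, "possible_maternal_cell_admixture")
      }
    }
    if (length(adj) || length(pop_frac)) {
      fr <- c(vapply(adj, function(a) a$fraction, numeric(1)), pop_frac)
      if (max(fr) - min(fr) > 0.15) {
        flags <- c(flags, "mosaic_population_fractions_divergent")
      }
      sp2 <- secondary_pop_spec(baseline, pop_sex, adj)
      populations <- list(list(spec = sp2, fraction = mean(fr),
                               kind = kind))
    }
  }

  # ---- final arithmetic and rendering ----------------------------------
  primary <- new_karyotype_spec(
    base_ploidy = baseline, sex = sex, gains = gains, losses = losses,
    events = struct_events
  )
  primary$count <- implied_count(primary)

  call <- structure(
    list(chromosome_count = primary$count, ploidy = pl$ploidy,
         baseline = baseline, sex_complement = sex, spec = primary,
         aberrations = struct_events, gains = gains, losses = losses,
         populations = populations, cells_analyzed = as.list(n_by_hyb),
         chromosome_calls = chromosome_calls, xy_call = xy_info,
         flags = unique(flags), icp_string = NA_character_),
    class = "icp_genome_call"
  )
  call$icp_string <- to_icp_string(call)
  call
}

#' Serialize a genome call to a report JSON
#'
#' @param call An `icp_genome_call`.
#' @param path Optional output path; when NULL the report list is returned.
#' @param seed,config Optional provenance echoed into the report so every
#'   output records what reproduces it.
#' @return The report list, invisibly when written to a file.
#' @export
genome_call_report <- function(call, path = NULL, seed = NULL, config = NULL) {
  report <- list(
    icp_string = call$icp_string,
    chromosome_count = call$chromosome_count,
    ploidy = call$ploidy,
    sex = format_sex(call$sex_complement),
    gains = call$gains, losses = call$losses,
    aberrations = lapply(call$aberrations, function(ev) {
      list(kind = ev$kind, chromosomes = ev$chromosomes,
           arms = ev$arms, bands = ev$bands, balanced = ev$balanced,
           extra_copy_of = ev$extra_copy_of,
           der_chromosome = ev$der_chromosome)
    }),
    populations = lapply(call$populations, function(p) {
      list(karyotype = render_karyotype(p$spec), fraction = p$fraction,
           kind = p$kind)
    }),
    cells_analyzed = call$cells_analyzed,
    flags = call$flags
  )
  if (!is.null(seed)) report$seed <- seed
  if (!is.null(config)) report$config <- unclass(config)
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
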