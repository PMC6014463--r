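# Per-hybridization calling: modal copy numbers with mosaicism thresholds,
# juxtaposition calls against the normal cut-off, displacement evidence and
# a per-chromosome interpretation.

#' Caller configuration
#'
#' @param min_cells Minimum cells per hybridization before a call is made
#'   without a low-cell-count warning (default 20).
#' @param mosaic_min_cells Minimum cells in a secondary population before
#'   mosaicism is reported (default 4, the "four of 20" rule).
#' @param mosaic_min_fraction Minimum secondary-population fraction
#'   (default 0.20); for n != 20 cells both thresholds must hold, a
#'   conservative extension of the four-of-20 rule.
#' @param fusion_cutoff Normal cut-off for juxtaposition of two signals:
#'   a fusion seen in strictly more than this fraction of nuclei is
#'   abnormal (default 0.20).
#' @param fusion_radius Spot clustering radius used at extraction; defaults
#'   to the simulator's fusion distance.
#' @param displaced_threshold Distance beyond which a terminal signal
#'   cluster counts as displaced from its nearest pericentromeric cluster,
#'   in nucleus radii. Must comfortably exceed the territory scatter.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_cells = 20L, mosaic_min_cells = 4L,
                          mosaic_min_fraction = 0.20, fusion_cutoff = 0.20,
                          fusion_radius = 0.05, displaced_threshold = 0.35) {
  stopifnot(
    mosaic_min_cells >= 2L,
    fusion_cutoff > 0, fusion_cutoff < 1,
    mosaic_min_fraction > 0, mosaic_min_fraction <= 1,
    fusion_radius > 0, displaced_threshold > 0
  )
  structure(
    list(min_cells = as.integer(min_cells),
         mosaic_min_cells = as.integer(mosaic_min_cells),
         mosaic_min_fraction = mosaic_min_fraction,
         fusion_cutoff = fusion_cutoff, fusion_radius = fusion_radius,
         displaced_threshold = displaced_threshold),
    class = "caller_config"
  )
}

# modal value with ties broken toward the diploid expectation 2, then the
# smaller count
modal_count <- function(counts) {
  tab <- table(counts)
  vals <- as.integer(names(tab))
  best <- vals[tab == max(tab)]
  best[order(abs(best - 2L), best)][1]
}

#' Call the copy number of one probe target
#'
#' The primary copy number is the modal per-cell signal count for the
#' target's color; a secondary (mosaic) population is reported only when
#' its cell count reaches `mosaic_min_cells` AND its fraction reaches
#' `mosaic_min_fraction`.
#'
#' @param patterns List of `icp_cell_pattern` (all cells of one
#'   hybridization).
#' @param color Target color, one of [ICP_COLORS].
#' @param config A [caller_config()].
#' @return An `icp_target_call`: primary/secondary copy number, secondary
#'   fraction, cell counts, and a `low_cells` flag when fewer than
#'   `min_cells` cells were available.
#' @export
call_copy_number <- function(patterns, color, config = caller_config()) {
  if (!length(patterns)) stop("no cells to call")
  color <- match.arg(color, ICP_COLORS)
  counts <- vapply(patterns, function(p) as.integer(p$color_counts[[color]]),
                   integer(1))
  n <- length(counts)
  primary <- modal_count(counts)
  tab <- table(counts)
  vals <- as.integer(names(tab))
  sec <- NA_integer_; sec_frac <- 0
  cand <- vals[vals != primary]
  if (length(cand)) {
    freq <- as.integer(tab[as.character(cand)])
    ok <- freq >= config$mosaic_min_cells &
      freq / n >= config$mosaic_min_fraction
    if (any(ok)) {
      cand <- cand[ok]; freq <- freq[ok]
      pick <- cand[order(-freq, abs(cand - 2L), cand)][1]
      sec <- pick
      sec_frac <- as.integer(tab[as.character(pick)]) / n
    }
  }
  structure(
    list(color = color, primary_copy_number = primary,
         secondary_copy_number = sec, secondary_fraction = sec_frac,
         n_cells = n, counts = counts,
         low_cells = n < config$min_cells),
    class = "icp_target_call"
  )
}

#' Call a two-color juxtaposition against the normal cut-off
#'
#' The fraction is the share of cells containing at least one fusion event
#' whose color set includes both colors; strictly more than
#' `fusion_cutoff` is abnormal (a fusion in exactly 20% of nuclei is still
#' within the normal cut-off).
#'
#' @param patterns List of `icp_cell_pattern`.
#' @param pair Character vector of two distinct colors.
#' @param config A [caller_config()].
#' @return An `icp_fusion_call` with `fraction`, `abnormal`, `n_cells`.
#' @export
call_fusion <- function(patterns, pair, config = caller_config()) {
  if (!length(patterns)) stop("no cells to call")
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1] == pair[2] ||
      !all(pair %in% ICP_COLORS)) {
    stop("pair must be two distinct colors")
  }
  fused <- vapply(patterns, function(p) {
    any(vapply(p$fusions, function(f) all(pair %in% f), logical(1)))
  }, logical(1))
  frac <- mean(fused)
  structure(
    list(color_pair = sort(pair), fraction = frac,
         abnormal = frac > config$fusion_cutoff, n_cells = length(patterns)),
    class = "icp_fusion_call"
  )
}

#' Estimate a laboratory normal cut-off from control samples
#'
#' Returns the larger of (a) the maximum per-control observed fusion
#' fraction and (b) the one-sided exact binomial (Clopper-Pearson) upper
#' confidence bound on the pooled fusion rate.
#'
#' @param controls List of control samples, each a list of
#'   `icp_cell_pattern`.
#' @param confidence One-sided confidence level for the binomial upper
#'   bound (default 0.95).
#' @param pair Optional two-color pair; by default any multi-color fusion
#'   event counts.
#' @return Proportion in (0, 1].
#' @export
estimate_cutoff <- function(controls, confidence = 0.95, pair = NULL) {
  if (!length(controls)) stop("at least one control sample is required")
  cell_fused <- function(p) {
    if (is.null(pair)) length(p$fusions) > 0L
    else any(vapply(p$fusions, function(f) all(pair %in% f), logical(1)))
  }
  fracs <- vapply(controls, function(patterns) {
    mean(vapply(patterns, cell_fused, logical(1)))
  }, numeric(1))
  x <- sum(vapply(controls, function(patterns) {
    sum(vapply(patterns, cell_fused, logical(1)))
  }, numeric(1)))
  n <- sum(vapply(controls, length, integer(1)))
  upper <- if (x >= n) 1 else stats::qbeta(confidence, x + 1, n - x)
  max(max(fracs), upper)
}

#' Displacement evidence for a terminal target
#'
#' Fraction of cells in which at least one cluster of the terminal color
#' lies farther than `displaced_threshold` from every cluster containing
#' the pericentromeric color — the interphase signature of a terminal
#' segment residing on another chromosome. Cells with no pericentromeric
#' cluster are not assessable and are skipped.
#'
#' @param patterns List of `icp_cell_pattern`.
#' @param terminal_color,cen_color Colors of the terminal and
#'   pericentromeric targets.
#' @param config A [caller_config()].
#' @return List with `fraction`, `abnormal` (fraction strictly above the
#'   fusion cut-off) and `n_assessable`.
#' @export
displacement_evidence <- function(patterns, terminal_color, cen_color,
                                  config = caller_config()) {
  flags <- vapply(patterns, function(p) {
    cl <- p$clusters
    has_cen <- grepl(cen_color, cl$colors, fixed = TRUE)
    has_term <- grepl(terminal_color, cl$colors, fixed = TRUE)
    if (!any(has_cen) || !any(has_term)) return(NA)
    any(vapply(which(has_term), function(i) {
      d <- sqrt((cl$x[i] - cl$x[has_cen])^2 + (cl$y[i] - cl$y[has_cen])^2)
      min(d) > config$displaced_threshold
    }, logical(1)))
  }, logical(1))
  n_ok <- sum(!is.na(flags))
  frac <- if (n_ok) mean(flags, na.rm = TRUE) else 0
  list(fraction = frac, abnormal = frac > config$fusion_cutoff,
       n_assessable = n_ok)
}

#' Interpret one chromosome's calls
#'
#' Combines target copy-number calls (pter/cen/qter), fusion calls and
#' displacement evidence into typed per-chromosome events relative to a
#' baseline copy number: uniform counts above/below baseline are GAIN/LOSS;
#' a terminal count below the pericentromeric count is a terminal deletion
#' of that arm; a terminal count above it, or a displaced terminal with
#' normal counts, is displaced-terminal evidence feeding translocation
#' assembly; an abnormal fusion is a FUSION event. A single event type
#' labels the chromosome; several together give MIXED with all evidence
#' retained.
#'
#' @param chromosome Chromosome identifier.
#' @param target_calls Named list of `icp_target_call` keyed by locus class
#'   ("PTER", "CEN", "QTER"; any subset).
#' @param fusion_calls List of `icp_fusion_call` (may be empty).
#' @param displaced Named list of displacement evidence keyed by arm
#'   ("p"/"q"), as returned by [displacement_evidence()].
#' @param baseline Expected copy number (genome baseline; 2 for a diploid
#'   autosome).
#' @param config A [caller_config()].
#' @return An `icp_chromosome_call` with `interpretation` in NORMAL, GAIN,
#'   LOSS, TERMINAL_DEL_P, TERMINAL_DEL_Q, FUSION, DISPLACED_TERMINAL or
#'   MIXED, an `events` list consumed by genome assembly, and
#'   `mosaic_populations` from the pericentromeric secondary call.
#' @export
interpret_chromosome <- function(chromosome, target_calls,
                                 fusion_calls = list(),
                                 displaced = list(), baseline = 2L,
                                 config = caller_config()) {
  cen <- target_calls$CEN$primary_copy_number
  if (is.null(cen)) stop("a pericentromeric (CEN) call is required")
  events <- list()
  labels <- character()

  d <- cen - baseline
  if (d > 0) {
    events <- c(events, lapply(seq_len(d), function(i)
      list(type = "GAIN", chromosome = chromosome)))
    labels <- c(labels, "GAIN")
  } else if (d < 0) {
    events <- c(events, lapply(seq_len(-d), function(i)
      list(type = "LOSS", chromosome = chromosome)))
    labels <- c(labels, "LOSS")
  }

  for (arm in c("p", "q")) {
    cls <- if (arm == "p") "PTER" else "QTER"
    tc <- target_calls[[cls]]
    if (is.null(tc)) next
    rel <- tc$primary_copy_number - cen
    disp <- displaced[[arm]]
    if (rel < 0) {
      events <- c(events, lapply(seq_len(-rel), function(i)
        list(type = "TERMINAL_DEL", chromosome = chromosome, arm = arm)))
      labels <- c(labels, if (arm == "p") "TERMINAL_DEL_P" else "TERMINAL_DEL_Q")
    } else if (rel > 0) {
      events <- c(events, lapply(seq_len(rel), function(i)
        list(type = "EXTRA_TERMINAL", chromosome = chromosome, arm = arm,
             displaced = !is.null(disp) && isTRUE(disp$abnormal))))
      labels <- c(labels, "DISPLACED_TERMINAL")
    } else if (!is.null(disp) && isTRUE(disp$abnormal)) {
      events <- c(events, list(list(type = "DISPLACED", chromosome = chromosome,
                                    arm = arm)))
      labels <- c(labels, "DISPLACED_TERMINAL")
    }
  }

  for (fc in fusion_calls) {
    if (isTRUE(fc$abnormal)) {
      events <- c(events, list(list(type = "FUSION", pair = fc$color_pair,
                                    fraction = fc$fraction)))
      labels <- c(labels, "FUSION")
    }
  }

  labels <- unique(labels)
  interpretation <- if (!length(labels)) "NORMAL"
    else if (length(labels) == 1L) labels
    else "MIXED"

  mosaic <- list()
  cen_call <- target_calls$CEN
  if (!is.na(cen_call$secondary_copy_number)) {
    mosaic <- list(list(copy_number = cen_call$secondary_copy_number,
                        fraction = cen_call$secondary_fraction))
  }

  structure(
    list(chromosome = chromosome, target_calls = target_calls,
         fusion_calls = fusion_calls, displaced = displaced,
         baseline = baseline, events = events,
         interpretation = interpretation, mosaic_populations = mosaic,
         n_cells = cen_call$n_cells),
    class = "icp_chromosome_call"
  )
}

#' @export
print.icp_chromosome_call <- function(x, ...) {
  counts <- vapply(x$target_calls, function(t) t$primary_copy_number,
                   integer(1))
  cat(sprintf("<icp_chromosome_call> chr%s [%s] %s (baseline %d, %d cells)\n",
              x$chromosome,
              paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
              x$interpretation, x$baseline, x$n_cells))
  invisible(x)
}

#' Refine a breakpoint from ordered band presence
#'
#' For a panel with one probe per band ordered centromere-to-telomere along
#' an arm, locates the breakpoint implied by a terminal run of absent
#' bands: the interval between the last present band and the first absent
#' band of that run.
#'
#' @param bands Data frame with columns `band_label` and `present`
#'   (logical), ordered centromere to telomere, or a list of
#'   `(band_label, present)` pairs.
#' @return List with `status` ("breakpoint", "none" when all bands are
#'   present, or "whole_arm" when all are absent), `proximal` (last present
#'   band or NA), `distal` (first absent band of the terminal run or NA)
#'   and `interstitial` (TRUE when absences occur proximal to present
#'   bands, which a terminal breakpoint cannot explain).
#' @export
refine_breakpoint <- function(bands) {
  if (is.list(bands) && !is.data.frame(bands)) {
    bands <- data.frame(
      band_label = vapply(bands, function(b) as.character(b[[1]]), character(1)),
      present = vapply(bands, function(b) as.logical(b[[2]]), logical(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!nrow(bands)) stop("band list must not be empty")
  pres <- bands$present
  n <- length(pres)
  if (all(pres)) {
    return(list(status = "none", proximal = NA_character_,
                distal = NA_character_, interstitial = FALSE))
  }
  # terminal run of absent bands
  last_present <- max(c(0L, which(pres)))
  first_absent <- last_present + 1L
  if (first_absent > n) {
    # absences are interstitial only; no terminal breakpoint
    return(list(status = "none", proximal = NA_character_,
                distal = NA_character_, interstitial = TRUE))
  }
  interstitial <- any(!pres[seq_len(last_present)])
  list(
    status = if (last_present == 0L) "whole_arm" else "breakpoint",
    proximal = if (last_present == 0L) NA_character_
               else bands$band_label[last_present],
    distal = bands$band_label[first_absent],
    interstitial = interstitial
  )
}
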