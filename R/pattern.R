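# Noise-free signal model: which spots a karyotype produces in a given
# hybridization, organized into chromosome territories and fusion groups.
#
# The layout is the shared ground truth for both the analytic expected
# pattern and the spot simulator: a territory corresponds to one physical
# chromosome (or derivative, or a translocated terminal fragment) and holds
# one or more signal groups; a group with two or more colors is a true
# fusion whose members always sit within the juxtaposition distance.

is_acro_style <- function(hyb) {
  length(hyb$chromosomes_covered) > 1L && all(hyb$targets$locus_class == "CEN")
}

target_row_for_arm <- function(targets, arm) {
  cls <- if (arm == "p") "PTER" else "QTER"
  which(targets$locus_class == cls)
}

signal_group <- function(colors, displaced = FALSE) {
  list(colors = colors, displaced = displaced)
}

territory <- function(groups, displaced = FALSE) {
  list(groups = groups, displaced = displaced)
}

#' Noise-free signal layout of a karyotype in one hybridization
#'
#' Internal workhorse behind [expected_pattern()] and the simulator. Returns
#' territories: one per chromosome copy, derivative chromosome, or displaced
#' terminal fragment, each containing signal groups (a multi-color group is
#' a true fusion).
#'
#' @param spec A `karyotype_spec`.
#' @param hyb An `icp_hybridization`.
#' @return List of territories. Chromosomes in the spec that the
#'   hybridization does not target contribute nothing (an empty layout is
#'   not an error).
#' @keywords internal
expected_signal_layout <- function(spec, hyb) {
  terrs <- list()
  add <- function(t) terrs[[length(terrs) + 1L]] <<- t
  acro_style <- is_acro_style(hyb)

  # Robertsonian derivatives fuse two pericentromeric colors in an
  # acrocentric-mix hybridization; elsewhere the der behaves as one normal
  # copy of each participant.
  consumed <- stats::setNames(rep(0L, length(hyb$chromosomes_covered)),
                              hyb$chromosomes_covered)
  if (acro_style) {
    for (ev in spec$events) {
      if (ev$kind != "ROBERTSONIAN") next
      a <- ev$chromosomes[1]; b <- ev$chromosomes[2]
      if (!all(c(a, b) %in% hyb$chromosomes_covered)) next
      col_a <- hyb$targets$color[hyb$targets$chromosome == a]
      col_b <- hyb$targets$color[hyb$targets$chromosome == b]
      add(territory(list(signal_group(c(col_a, col_b)))))
      consumed[a] <- consumed[a] + 1L
      consumed[b] <- consumed[b] + 1L
    }
  }

  for (chr in hyb$chromosomes_covered) {
    tg <- hyb$targets[hyb$targets$chromosome == chr, , drop = FALSE]
    n <- copy_number(spec, chr)
    mods <- list()       # per-copy modifications consuming one copy each
    for (ev in spec$events) {
      if (ev$kind == "TERMINAL_DELETION" && ev$chromosomes[1] == chr) {
        mods <- c(mods, list(list(type = "del", arm = ev$arms[1])))
      } else if (ev$kind == "RECIPROCAL_TRANSLOCATION" &&
                 chr %in% ev$chromosomes) {
        i <- match(chr, ev$chromosomes)
        arm <- ev$arms[i]
        if (is.na(arm)) arm <- "q"   # breakpoint arm unstated; assume q
        mods <- c(mods, list(list(type = "transloc_out", arm = arm)))
      } else if (ev$kind == "UNBALANCED_DER") {
        i <- match(chr, ev$chromosomes)
        if (identical(chr, ev$der_chromosome)) {
          arm <- ev$arms[i]
          if (is.na(arm)) arm <- "q"
          mods <- c(mods, list(list(type = "del", arm = arm)))
        } else if (!is.na(i)) {
          # partner: its terminal segment also rides on the derivative,
          # displaced away from the partner's own territories
          arm <- ev$arms[i]
          if (is.na(arm)) arm <- "q"
          mods <- c(mods, list(list(type = "extra_displaced", arm = arm)))
        }
      }
    }
    n_consuming <- sum(vapply(mods, function(m)
      m$type %in% c("del", "transloc_out"), logical(1)))
    n_free <- n - n_consuming - consumed[[chr]] %||% 0L
    if (is.na(n_free) || n_free < 0) {
      stop("karyotype events consume more copies of chromosome ", chr,
           " than exist")
    }
    for (i in seq_len(n_free)) {
      add(territory(lapply(tg$color, signal_group)))
    }
    for (m in mods) {
      idx <- target_row_for_arm(tg, m$arm)
      if (m$type == "del") {
        keep <- setdiff(seq_len(nrow(tg)), idx)
        if (length(keep)) {
          add(territory(lapply(tg$color[keep], signal_group)))
        }
        # deleting an arm with no probe (acrocentric p) leaves the copy intact
        if (length(idx) == 0L) add(territory(lapply(tg$color, signal_group)))
      } else if (m$type == "transloc_out") {
        keep <- setdiff(seq_len(nrow(tg)), idx)
        add(territory(lapply(tg$color[keep], signal_group)))
        if (length(idx)) {
          add(territory(list(signal_group(tg$color[idx], displaced = TRUE)),
                        displaced = TRUE))
        }
      } else if (m$type == "extra_displaced") {
        if (length(idx)) {
          add(territory(list(signal_group(tg$color[idx], displaced = TRUE)),
                        displaced = TRUE))
        }
      }
    }
  }
  terrs
}

#' Expected noise-free signal pattern
#'
#' Computes the per-cell signal multiset a karyotype produces in one
#' hybridization: per-color signal counts and true fusion events. Counts
#' equal the copy number of each targeted locus; a Robertsonian derivative
#' contributes one fused two-color pericentromeric signal in the acrocentric
#' mix; terminal deletions decrement the deleted arm's terminal color;
#' unbalanced derivatives move a terminal signal between hybridizations.
#'
#' @param spec A `karyotype_spec` (or karyotype string).
#' @param hyb An `icp_hybridization`.
#' @return List with `color_counts` (named integer vector over [ICP_COLORS])
#'   and `fusions` (list of sorted color vectors, one per fusion event).
#' @export
expected_pattern <- function(spec, hyb) {
  if (is.character(spec)) spec <- parse_karyotype_spec(spec)
  layout <- expected_signal_layout(spec, hyb)
  counts <- stats::setNames(rep(0L, length(ICP_COLORS)), ICP_COLORS)
  fusions <- list()
  for (terr in layout) {
    for (g in terr$groups) {
      for (col in g$colors) counts[col] <- counts[col] + 1L
      if (length(unique(g$colors)) >= 2L) {
        fusions <- c(fusions, list(sort(unique(g$colors))))
      }
    }
  }
  list(color_counts = counts, fusions = fusions)
}
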