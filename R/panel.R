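# Probe-panel model: targets, hybridizations and the two built-in panels.

#' Fluorophore palette
#'
#' The five colors used across both probe sets. Every probe target and every
#' detected spot carries exactly one of these labels.
#'
#' @export
ICP_COLORS <- c("AQUA", "GREEN", "YELLOW", "RED", "FARRED")

#' Acrocentric chromosomes
#'
#' The five human acrocentric autosomes; the only chromosomes that can
#' participate in a Robertsonian translocation.
#'
#' @export
ACROCENTRICS <- c("13", "14", "15", "21", "22")

#' All chromosome identifiers
#' @export
CHROMOSOMES <- c(as.character(1:22), "X", "Y")

LOCUS_CLASSES <- c("PTER", "CEN", "QTER", "BAND")

chrom_rank <- function(chromosome) {
  match(as.character(chromosome), CHROMOSOMES)
}

#' Construct a probe target
#'
#' @param chromosome Chromosome identifier ("1".."22", "X", "Y").
#' @param arm Arm carrying the target: "p", "q" or "centromeric".
#' @param locus_class One of "PTER", "CEN", "QTER", "BAND".
#' @param color One of [ICP_COLORS].
#' @param band_label Free-text band designation; required (non-empty) when
#'   `locus_class` is "BAND", treated as opaque text otherwise.
#' @return A one-row data frame with columns chromosome, arm, locus_class,
#'   band_label, color.
#' @export
probe_target <- function(chromosome, arm, locus_class, color, band_label = "") {
  chromosome <- as.character(chromosome)
  if (!chromosome %in% CHROMOSOMES) {
    stop("unknown chromosome: ", chromosome)
  }
  if (!arm %in% c("p", "q", "centromeric")) {
    stop("arm must be 'p', 'q' or 'centromeric', got: ", arm)
  }
  if (!locus_class %in% LOCUS_CLASSES) {
    stop("unknown locus_class: ", locus_class)
  }
  if (!color %in% ICP_COLORS) {
    stop("unknown color: ", color)
  }
  if (locus_class == "BAND" && !nzchar(band_label)) {
    stop("locus_class 'BAND' requires a non-empty band_label")
  }
  data.frame(
    chromosome = chromosome, arm = arm, locus_class = locus_class,
    band_label = band_label, color = color, stringsAsFactors = FALSE
  )
}

#' Construct a hybridization
#'
#' One hybridization is the set of probe targets applied to a slide area
#' together; each autosome gets its own hybridization in the Standard panel
#' while X and Y share one.
#'
#' @param id Hybridization identifier, e.g. `"chr7"`.
#' @param targets Data frame of probe targets (rows from [probe_target()]).
#' @return An object of class `icp_hybridization`.
#' @export
hybridization <- function(id, targets) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  targets <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    probe_target(
      targets$chromosome[i], targets$arm[i], targets$locus_class[i],
      targets$color[i], targets$band_label[i]
    )
  }))
  key <- paste(targets$chromosome, targets$locus_class, targets$band_label)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, locus_class, band_label) in hybridization ", id)
  }
  # Two same-chromosome targets sharing a color would be indistinguishable.
  cc <- paste(targets$chromosome, targets$color)
  if (anyDuplicated(cc)) {
    stop("two targets on one chromosome share a color in hybridization ", id)
  }
  structure(
    list(
      id = id,
      targets = targets,
      chromosomes_covered = sort(unique(targets$chromosome))
    ),
    class = "icp_hybridization"
  )
}

#' Construct a panel
#'
#' @param name Panel name.
#' @param hybridizations Ordered list of [hybridization()] objects.
#' @return An object of class `icp_panel`; hybridizations are accessible by id.
#' @export
icp_panel <- function(name, hybridizations) {
  ids <- vapply(hybridizations, function(h) h$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate hybridization ids in panel ", name)
  names(hybridizations) <- ids
  structure(list(name = name, hybridizations = hybridizations),
            class = "icp_panel")
}

#' @export
print.icp_panel <- function(x, ...) {
  nt <- sum(vapply(x$hybridizations, function(h) nrow(h$targets), integer(1)))
  cat(sprintf("<icp_panel> %s: %d hybridizations, %d probe targets\n",
              x$name, length(x$hybridizations), nt))
  invisible(x)
}

#' @export
print.icp_hybridization <- function(x, ...) {
  cat(sprintf("<icp_hybridization> %s: %s\n", x$id,
              paste(x$chromosomes_covered, collapse = ",")))
  print(x$targets)
  invisible(x)
}

standard_targets_for <- function(chromosome) {
  if (chromosome == "Y") {
    rbind(
      probe_target("Y", "p", "PTER", "AQUA"),
      probe_target("Y", "centromeric", "CEN", "YELLOW"),
      probe_target("Y", "q", "QTER", "RED")
    )
  } else if (chromosome %in% ACROCENTRICS) {
    # Acrocentric short arms carry no probe.
    rbind(
      probe_target(chromosome, "centromeric", "CEN", "YELLOW"),
      probe_target(chromosome, "q", "QTER", "RED")
    )
  } else {
    rbind(
      probe_target(chromosome, "p", "PTER", "GREEN"),
      probe_target(chromosome, "centromeric", "CEN", "YELLOW"),
      probe_target(chromosome, "q", "QTER", "RED")
    )
  }
}

#' Build the Standard Resolution panel
#'
#' 23 hybridizations: one per autosome plus a joint X/Y hybridization.
#' Non-acrocentric chromosomes carry a GREEN p-subtelomere, YELLOW
#' pericentromeric and RED q-subtelomere probe; acrocentrics lack the p-arm
#' probe; the Y short arm is AQUA so that X and Y can be counted separately
#' in the shared hybridization.
#'
#' @return An `icp_panel` with hybridizations `chr1`..`chr22` and `chrXY`.
#' @export
build_standard_panel <- function() {
  hybs <- lapply(as.character(1:22), function(chr) {
    hybridization(paste0("chr", chr), standard_targets_for(chr))
  })
  hybs <- c(hybs, list(hybridization(
    "chrXY",
    rbind(standard_targets_for("X"), standard_targets_for("Y"))
  )))
  icp_panel("StandardResolution", hybs)
}

#' Build the Acrocentric panel
#'
#' One hybridization with a distinctly colored pericentromeric probe for each
#' acrocentric chromosome (13 YELLOW, 14 GREEN, 15 RED, 21 AQUA, 22 FARRED);
#' no other loci are targeted. Consistent juxtaposition of two of these
#' colors is the interphase signature of a Robertsonian translocation.
#'
#' @return An `icp_panel` with the single hybridization `acro`.
#' @export
build_acrocentric_panel <- function() {
  colors <- c("13" = "YELLOW", "14" = "GREEN", "15" = "RED",
              "21" = "AQUA", "22" = "FARRED")
  targets <- do.call(rbind, lapply(ACROCENTRICS, function(chr) {
    probe_target(chr, "centromeric", "CEN", colors[[chr]])
  }))
  icp_panel("Acrocentric", list(hybridization("acro", targets)))
}

#' Color-to-chromosome map of the Acrocentric panel
#'
#' @param panel An acrocentric `icp_panel` (default: built-in).
#' @return Named character vector mapping color to chromosome.
#' @export
acro_color_map <- function(panel = build_acrocentric_panel()) {
  t <- panel$hybridizations[[1]]$targets
  stats::setNames(t$chromosome, t$color)
}

#' Write a panel to JSON
#'
#' Serializes name, hybridization ids and targets so the built-in panels (or
#' any user-defined panel) round-trip bit-exactly through [read_panel_json()].
#'
#' @param panel An `icp_panel`.
#' @param path Output file path.
#' @export
write_panel_json <- function(panel, path) {
  obj <- list(
    name = panel$name,
    hybridizations = lapply(panel$hybridizations, function(h) {
      list(id = h$id, targets = h$targets)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a panel from JSON
#'
#' @param path File written by [write_panel_json()] or following the same
#'   schema.
#' @return An `icp_panel`.
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  hybs <- obj$hybridizations
  if (is.data.frame(hybs)) hybs <- split(hybs, seq_len(nrow(hybs)))
  hy <- lapply(hybs, function(h) {
    tg <- as.data.frame(h$targets)
    if (!"band_label" %in% names(tg)) tg$band_label <- ""
    tg$band_label[is.na(tg$band_label)] <- ""
    hybridization(h$id, tg)
  })
  icp_panel(obj$name, unname(hy))
}
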