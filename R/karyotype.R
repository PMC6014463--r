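# Karyotype mini-language: parsing, validation and rendering of the
# cytogenetic-style strings used both as simulator input and as the "icp."
# nomenclature emitted by the genome-call assembler.
#
# Two dialects are supported:
#   * structured  -- "46,XY,der(13;14)(q10;q10),+14", optionally prefixed
#     "icp." and suffixed "[cpN]", populations joined by "/";
#   * descriptive -- validation-table shorthand such as "Trisomy 16",
#     "Monosomy X,del(17q)" or "+21,der t(14;21)".
# Band labels inside parentheses (including "?") are carried as opaque text.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a structural event
#'
#' @param kind One of "TERMINAL_DELETION", "RECIPROCAL_TRANSLOCATION",
#'   "UNBALANCED_DER", "ROBERTSONIAN".
#' @param chromosomes Chromosomes involved (ascending order for two-chromosome
#'   events). For "UNBALANCED_DER" these are the two translocation partners.
#' @param arms Arm letters ("p"/"q") aligned with `chromosomes`; may contain
#'   NA when unknown.
#' @param bands Opaque band-label text aligned with `chromosomes` (e.g.
#'   `c("q10","q10")`, `c("p?","q?")`); NULL when the source string carried
#'   no band block.
#' @param balanced Logical; FALSE for events implying net genomic imbalance.
#' @param extra_copy_of For an unbalanced Robertsonian, the participant
#'   present in an extra copy (translocation trisomy).
#' @param der_chromosome For "UNBALANCED_DER", the chromosome whose copy is
#'   the derivative.
#' @return A list of class `icp_event`.
#' @export
structural_event <- function(kind, chromosomes, arms = NULL, bands = NULL,
                             balanced = NA, extra_copy_of = NULL,
                             der_chromosome = NULL) {
  kind <- match.arg(kind, c("TERMINAL_DELETION", "RECIPROCAL_TRANSLOCATION",
                            "UNBALANCED_DER", "ROBERTSONIAN"))
  chromosomes <- as.character(chromosomes)
  if (kind == "ROBERTSONIAN") {
    if (length(chromosomes) != 2L || !all(chromosomes %in% ACROCENTRICS)) {
      stop("ROBERTSONIAN participants must be two acrocentric chromosomes")
    }
    ord <- order(chrom_rank(chromosomes))
    chromosomes <- chromosomes[ord]
  }
  if (kind == "RECIPROCAL_TRANSLOCATION" && length(chromosomes) != 2L) {
    stop("RECIPROCAL_TRANSLOCATION requires exactly two participants")
  }
  structure(
    list(kind = kind, chromosomes = chromosomes, arms = arms, bands = bands,
         balanced = balanced, extra_copy_of = extra_copy_of,
         der_chromosome = der_chromosome),
    class = "icp_event"
  )
}

# Normalize raw nomenclature text: unicode minus / dashes to "-", collapse
# whitespace after commas (the tables are inconsistent in spacing).
normalize_karyotype_text <- function(text) {
  x <- trimws(text)
  x <- gsub("[−–—]", "-", x)
  x <- gsub(" ", " ", x)
  x <- gsub(",[ \t]+", ",", x)
  x
}

arm_of_band <- function(band) {
  m <- regmatches(band, regexpr("[pq]", band))
  if (length(m) == 0L) NA_character_ else m
}

chrom_re <- "(?:[0-9]{1,2}|X|Y)"

# Parse one comma-separated event token; returns a tagged list or errors.
parse_event_token <- function(tok) {
  grab <- function(pattern) {
    m <- regmatches(tok, regexec(pattern, tok, perl = TRUE))[[1]]
    if (length(m)) m[-1] else NULL
  }
  if (!is.null(m <- grab(paste0("^\\+(", chrom_re, ")$")))) {
    return(list(type = "gain", chromosome = m[1]))
  }
  if (!is.null(m <- grab(paste0("^-(", chrom_re, ")$")))) {
    return(list(type = "loss", chromosome = m[1]))
  }
  if (!is.null(m <- grab(paste0("^del\\((", chrom_re, ")\\)\\(([^)]+)\\)$")))) {
    return(list(type = "event", event = structural_event(
      "TERMINAL_DELETION", m[1], arms = arm_of_band(m[2]), bands = m[2],
      balanced = FALSE
    )))
  }
  if (!is.null(m <- grab(paste0("^del\\((", chrom_re, ")([pq])[^)]*\\)$")))) {
    # compact shorthand: del(17q), del(Xq)
    return(list(type = "event", event = structural_event(
      "TERMINAL_DELETION", m[1], arms = m[2], bands = paste0(m[2], "?"),
      balanced = FALSE
    )))
  }
  if (!is.null(m <- grab(paste0(
    "^der\\((", chrom_re, ")\\)t\\((", chrom_re, ");(", chrom_re,
    ")\\)(?:\\(([^;)]+);([^;)]+)\\))?$"
  )))) {
    bands <- if (!is.na(m[4]) && nzchar(m[4])) c(m[4], m[5]) else NULL
    arms <- if (is.null(bands)) c(NA_character_, NA_character_) else
      vapply(bands, arm_of_band, character(1), USE.NAMES = FALSE)
    return(list(type = "event", event = structural_event(
      "UNBALANCED_DER", c(m[2], m[3]), arms = arms, bands = bands,
      balanced = FALSE, der_chromosome = m[1]
    )))
  }
  if (!is.null(m <- grab(paste0(
    "^der ?t?\\(([0-9]{1,2});([0-9]{1,2})\\)(?:\\(([^;)]+);([^;)]+)\\))?$"
  )))) {
    # der(13;14)(q10;q10), der(14;21), and the shorthand "der t(14;21)"
    if (all(c(m[1], m[2]) %in% ACROCENTRICS)) {
      bands <- if (!is.na(m[3]) && nzchar(m[3])) c(m[3], m[4]) else NULL
      return(list(type = "event", event = structural_event(
        "ROBERTSONIAN", c(m[1], m[2]), bands = bands, balanced = TRUE
      )))
    }
    stop("whole-arm der(", m[1], ";", m[2],
         ") requires two acrocentric chromosomes")
  }
  if (!is.null(m <- grab(paste0(
    "^t\\((", chrom_re, ");(", chrom_re, ")\\)(?:\\(([^;)]+);([^;)]+)\\))?$"
  )))) {
    bands <- if (!is.na(m[3]) && nzchar(m[3])) c(m[3], m[4]) else NULL
    both_acro <- all(c(m[1], m[2]) %in% ACROCENTRICS)
    centromeric <- is.null(bands) || all(grepl("^[pq]10$", bands))
    if (both_acro && centromeric) {
      # centromeric fusion of two acrocentrics written with "t" shorthand
      return(list(type = "event", event = structural_event(
        "ROBERTSONIAN", c(m[1], m[2]), bands = bands, balanced = TRUE
      )))
    }
    arms <- if (is.null(bands)) c(NA_character_, NA_character_) else
      vapply(bands, arm_of_band, character(1), USE.NAMES = FALSE)
    ord <- order(chrom_rank(c(m[1], m[2])))
    return(list(type = "event", event = structural_event(
      "RECIPROCAL_TRANSLOCATION", c(m[1], m[2])[ord], arms = arms[ord],
      bands = if (is.null(bands)) NULL else bands[ord], balanced = TRUE
    )))
  }
  stop("cannot parse karyotype token: '", tok, "'")
}

parse_sex_token <- function(tok) {
  if (grepl("or", tok, fixed = TRUE)) {
    alts <- trimws(strsplit(tok, "or", fixed = TRUE)[[1]])
    bad <- alts[!grepl("^[XY]*$", alts)]
    if (length(bad)) stop("cannot parse sex token: '", tok, "'")
    chosen <- alts[nzchar(alts)][1]
    list(sex = strsplit(chosen, "")[[1]], alternatives = alts, raw = tok)
  } else {
    if (!grepl("^[XY]+$", tok)) stop("cannot parse sex token: '", tok, "'")
    list(sex = strsplit(tok, "")[[1]], alternatives = tok, raw = tok)
  }
}

# Net change in modeled chromosome number contributed by gains/losses/events.
count_delta <- function(gains, losses, events) {
  d <- length(gains) - length(losses)
  for (ev in events) {
    if (ev$kind == "ROBERTSONIAN") {
      d <- d - 1L                       # two centromeric regions on one der
      if (!is.null(ev$extra_copy_of)) d <- d + 1L
    }
  }
  d
}

new_karyotype_spec <- function(base_ploidy, sex, gains = character(),
                               losses = character(), events = list(),
                               count = NA_integer_, sex_raw = NULL,
                               sex_alternatives = NULL, dialect = "structured",
                               raw = NULL, annotations = list(),
                               flags = character()) {
  structure(
    list(base_ploidy = as.integer(base_ploidy), sex = sex,
         gains = as.character(gains), losses = as.character(losses),
         events = events, count = as.integer(count),
         sex_raw = sex_raw %||% format_sex(sex),
         sex_alternatives = sex_alternatives %||% format_sex(sex),
         dialect = dialect, raw = raw, annotations = annotations,
         flags = flags),
    class = "karyotype_spec"
  )
}

# sort X before Y, e.g. c("X","X","Y") -> "XXY"
format_sex <- function(sex) {
  paste(c(rep("X", sum(sex == "X")), rep("Y", sum(sex == "Y"))), collapse = "")
}

parse_structured_clone <- function(text, strict = TRUE) {
  toks <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(toks) < 2L) {
    stop("karyotype string needs at least a count and a sex token: '",
         text, "'")
  }
  count <- suppressWarnings(as.integer(toks[1]))
  if (is.na(count)) stop("cannot parse chromosome count: '", toks[1], "'")
  sx <- parse_sex_token(toks[2])
  gains <- character(); losses <- character(); events <- list()
  for (tok in toks[-(1:2)]) {
    p <- parse_event_token(tok)
    if (p$type == "gain") gains <- c(gains, p$chromosome)
    else if (p$type == "loss") losses <- c(losses, p$chromosome)
    else events <- c(events, list(p$event))
  }
  # A "+N" following a Robertsonian der involving N is the translocation
  # trisomy: fold it into the event as extra_copy_of.
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$kind == "ROBERTSONIAN" && is.null(ev$extra_copy_of)) {
      hit <- which(gains %in% ev$chromosomes)[1]
      if (!is.na(hit)) {
        ev$extra_copy_of <- gains[hit]
        ev$balanced <- FALSE
        events[[i]] <- ev
        gains <- gains[-hit]
      }
    }
  }
  # X/Y gains/losses belong in the sex complement
  if (any(c(gains, losses) %in% c("X", "Y"))) {
    sex <- sx$sex
    for (g in gains[gains %in% c("X", "Y")]) sex <- c(sex, g)
    for (l in losses[losses %in% c("X", "Y")]) sex <- sex[-match(l, sex)]
    sx$sex <- sex
  }
  auto_gains <- gains[!gains %in% c("X", "Y")]
  auto_losses <- losses[!losses %in% c("X", "Y")]

  delta <- count_delta(auto_gains, auto_losses, events) +
    sum(gains %in% c("X", "Y")) - sum(losses %in% c("X", "Y"))
  n_sex <- max(nchar(sx$alternatives))
  ploidy <- (count - delta - n_sex) / 22
  flags <- character()
  if (ploidy != round(ploidy) || ploidy < 1) {
    implied <- 22 * round(max(1, (count - n_sex) / 23)) + n_sex + delta
    msg <- sprintf(
      "chromosome count %d inconsistent with sex/events (implies %d)",
      count, as.integer(implied))
    if (strict) stop(msg)
    flags <- c(flags, "count_mismatch")
    ploidy <- round(max(1, (count - n_sex) / 23))
  }
  spec <- new_karyotype_spec(
    base_ploidy = ploidy, sex = sx$sex, gains = auto_gains,
    losses = auto_losses, events = events, count = count,
    sex_raw = sx$raw, sex_alternatives = sx$alternatives,
    dialect = "structured", raw = text, flags = flags
  )
  validate_karyotype_spec(spec, strict = strict)
  spec
}

validate_karyotype_spec <- function(spec, strict = TRUE) {
  for (chr in unique(spec$losses)) {
    avail <- spec$base_ploidy - sum(spec$losses == chr)
    if (avail < 0) {
      stop("losses of chromosome ", chr, " exceed available copies")
    }
  }
  for (ev in spec$events) {
    if (ev$kind == "TERMINAL_DELETION" &&
        copy_number(spec, ev$chromosomes[1]) < 1) {
      stop("terminal deletion on absent chromosome ", ev$chromosomes[1])
    }
  }
  invisible(spec)
}

#' Total copy number of a chromosome under a karyotype spec
#'
#' Counts every copy of the chromosome's centromeric region, including
#' copies residing on derivative chromosomes.
#'
#' @param spec A `karyotype_spec`.
#' @param chromosome Chromosome identifier.
#' @return Integer copy number.
#' @export
copy_number <- function(spec, chromosome) {
  chromosome <- as.character(chromosome)
  if (chromosome %in% c("X", "Y")) {
    return(sum(spec$sex == chromosome))
  }
  n <- spec$base_ploidy + sum(spec$gains == chromosome) -
    sum(spec$losses == chromosome)
  for (ev in spec$events) {
    if (ev$kind == "ROBERTSONIAN" &&
        identical(ev$extra_copy_of, chromosome)) {
      n <- n + 1L
    }
  }
  as.integer(n)
}

#' Parse a karyotype specification string
#'
#' Accepts the plain cytogenetic column form ("47,XX,+16") as well as
#' "icp."-prefixed strings; the prefix and any "[cpN]" suffix are stripped
#' before parsing. Mosaic strings with "/" are rejected here — use
#' [parse_icp_string()] for multi-population calls.
#'
#' @param text Karyotype string.
#' @param strict If TRUE (default), an inconsistency between the leading
#'   chromosome count and the listed events is an error; if FALSE it is
#'   recorded in the spec's `flags` and the ploidy implied by the events is
#'   used.
#' @return A `karyotype_spec` with base ploidy, sex complement, gain/loss
#'   multisets and structural events.
#' @export
parse_karyotype_spec <- function(text, strict = TRUE) {
  x <- normalize_karyotype_text(text)
  x <- sub("^icp\\.", "", x)
  x <- sub("\\[cp[0-9]+\\]$", "", x)
  if (grepl("/", x, fixed = TRUE)) {
    stop("multi-population string; parse_karyotype_spec handles one clone ",
         "(use parse_icp_string)")
  }
  parse_structured_clone(x, strict = strict)
}

render_event <- function(ev) {
  band_block <- function(bands) {
    if (is.null(bands)) "" else paste0("(", paste(bands, collapse = ";"), ")")
  }
  switch(ev$kind,
    TERMINAL_DELETION = paste0("del(", ev$chromosomes[1], ")",
                               band_block(ev$bands %||% "?")),
    ROBERTSONIAN = paste0("der(", ev$chromosomes[1], ";", ev$chromosomes[2],
                          ")", band_block(ev$bands)),
    UNBALANCED_DER = paste0("der(", ev$der_chromosome, ")t(",
                            ev$chromosomes[1], ";", ev$chromosomes[2], ")",
                            band_block(ev$bands)),
    RECIPROCAL_TRANSLOCATION = paste0("t(", ev$chromosomes[1], ";",
                                      ev$chromosomes[2], ")",
                                      band_block(ev$bands))
  )
}

event_sort_key <- function(rendered, chromosomes) {
  # Events sort by the lowest chromosome involved, structural rearrangements
  # before plain gains/losses on the same chromosome.
  structural <- !grepl("^[+-]", rendered)
  sprintf("%02d-%d-%s", min(chrom_rank(chromosomes)), ifelse(structural, 0, 1),
          rendered)
}

#' Render a karyotype spec as nomenclature text
#'
#' @param spec A `karyotype_spec`.
#' @param prefix Prepend "icp." when TRUE.
#' @param cp Optional cell count for a trailing "[cpN]" suffix.
#' @return Canonical single-clone karyotype string. Events are ordered by
#'   lowest chromosome involved with structural events before gains/losses;
#'   the translocation trisomy of an unbalanced Robertsonian renders as
#'   "der(a;b)...,+c".
#' @export
render_karyotype <- function(spec, prefix = FALSE, cp = NULL) {
  if (identical(spec$dialect, "descriptive")) {
    out <- spec$raw
  } else {
    pieces <- character()
    keys <- character()
    for (ev in spec$events) {
      r <- render_event(ev)
      pieces <- c(pieces, r)
      keys <- c(keys, event_sort_key(r, ev$chromosomes))
      if (ev$kind == "ROBERTSONIAN" && !is.null(ev$extra_copy_of)) {
        r2 <- paste0("+", ev$extra_copy_of)
        pieces <- c(pieces, r2)
        keys <- c(keys, event_sort_key(r2, ev$extra_copy_of))
      }
    }
    for (g in spec$gains) {
      r <- paste0("+", g)
      pieces <- c(pieces, r); keys <- c(keys, event_sort_key(r, g))
    }
    for (l in spec$losses) {
      r <- paste0("-", l)
      pieces <- c(pieces, r); keys <- c(keys, event_sort_key(r, l))
    }
    pieces <- pieces[order(keys)]
    count <- spec$count
    if (is.na(count)) count <- implied_count(spec)
    out <- paste(c(count, spec$sex_raw, pieces), collapse = ",")
  }
  if (prefix) out <- paste0("icp.", out)
  if (!is.null(cp)) out <- paste0(out, "[cp", cp, "]")
  out
}

#' Chromosome count implied by a spec's ploidy, sex and events
#' @param spec A `karyotype_spec`.
#' @return Integer chromosome count.
#' @export
implied_count <- function(spec) {
  as.integer(22L * spec$base_ploidy + length(spec$sex) +
               count_delta(spec$gains, spec$losses, spec$events))
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat("<karyotype_spec> ", render_karyotype(x), "\n", sep = "")
  cat("  ploidy ", x$base_ploidy, ", sex ", format_sex(x$sex), sep = "")
  if (length(x$gains)) cat(", gains ", paste(x$gains, collapse = ","), sep = "")
  if (length(x$losses)) cat(", losses ", paste(x$losses, collapse = ","), sep = "")
  if (length(x$events)) cat(", ", length(x$events), " structural event(s)", sep = "")
  cat("\n")
  invisible(x)
}
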