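# "icp." nomenclature strings: multi-population parsing, rendering,
# normal/abnormal classification and karyotype-class comparison.

parse_descriptive_clone <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  phrase <- parts[1]
  ev_toks <- parts[-1]
  ploidy <- 2L; sex <- NULL; gains <- character(); losses <- character()
  annotations <- list()
  if (grepl("^[+-]|^der|^t\\(|^del", phrase)) {
    ev_toks <- parts                   # event-only shorthand like "+14"
  } else if (grepl("^Normal( female| male)?$", phrase)) {
    if (grepl("female", phrase)) sex <- c("X", "X")
    if (grepl(" male", phrase)) sex <- c("X", "Y")
  } else if (grepl("^Triploid", phrase)) {
    ploidy <- 3L
  } else if (!is.null(m <- match_groups(phrase,
      "^Tetraploid( \\(mosaic( ([0-9]+)%)?\\))?$"))) {
    ploidy <- 4L
    if (nzchar(m[1])) {
      annotations$mosaic <- TRUE
      if (nzchar(m[3])) annotations$mosaic_fraction <- as.numeric(m[3]) / 100
    }
  } else if (!is.null(m <- match_groups(phrase,
      "^Trisomy ([0-9]{1,2}|X|Y)( \\(([0-9]+) cells\\))?$"))) {
    gains <- m[1]
    if (nzchar(m[3])) annotations$cells <- as.integer(m[3])
  } else if (grepl("^Monosomy X$", phrase)) {
    sex <- "X"
  } else {
    stop("cannot parse karyotype phrase: '", phrase, "'")
  }
  events <- list()
  for (tok in ev_toks) {
    p <- parse_event_token(tok)
    if (p$type == "gain") gains <- c(gains, p$chromosome)
    else if (p$type == "loss") losses <- c(losses, p$chromosome)
    else events <- c(events, list(p$event))
  }
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$kind == "ROBERTSONIAN" && is.null(ev$extra_copy_of)) {
      hit <- which(gains %in% ev$chromosomes)[1]
      if (!is.na(hit)) {
        ev$extra_copy_of <- gains[hit]; ev$balanced <- FALSE
        events[[i]] <- ev; gains <- gains[-hit]
      }
    }
  }
  new_karyotype_spec(
    base_ploidy = ploidy, sex = sex %||% character(),
    gains = gains[!gains %in% c("X", "Y")],
    losses = losses[!losses %in% c("X", "Y")], events = events,
    sex_raw = if (is.null(sex)) "" else format_sex(sex),
    sex_alternatives = if (is.null(sex)) NA_character_ else format_sex(sex),
    dialect = "descriptive", raw = text, annotations = annotations
  )
}

match_groups <- function(x, pattern) {
  m <- regmatches(x, regexec(pattern, x, perl = TRUE))[[1]]
  if (length(m)) m[-1] else NULL
}

#' Parse an "icp." result string
#'
#' Understands the structured dialect ("icp.46,XY,der(13;14)(q10;q10),+14",
#' with optional "icp." prefix, "[cpN]" suffix and "/"-joined mosaic
#' populations) and the descriptive validation-table shorthand ("Trisomy 16",
#' "Monosomy X,del(17q)", "Normal male/female", "+21,der t(14;21)").
#'
#' @param text Result string.
#' @param strict If TRUE, a chromosome count inconsistent with the listed
#'   events is an error; if FALSE (default here, since some printed strings
#'   carry inconsistent counts) it is recorded in the clone's `flags`.
#' @return An object of class `icp_call`: list with `populations` (list of
#'   `karyotype_spec`), `cp` (cells analyzed or NA), `has_prefix`, `dialect`,
#'   and the normalized source text.
#' @export
parse_icp_string <- function(text, strict = FALSE) {
  norm <- normalize_karyotype_text(text)
  has_prefix <- grepl("^icp\\.", norm)
  body <- sub("^icp\\.", "", norm)
  cp <- NA_integer_
  m <- match_groups(body, "^(.*)\\[cp([0-9]+)\\]$")
  if (!is.null(m)) {
    body <- m[1]
    cp <- as.integer(m[2])
  }
  if (!nzchar(body)) stop("empty karyotype string")
  descriptive <- !grepl("^[0-9]", body)
  if (descriptive) {
    if (identical(body, "Normal male/female")) {
      pops <- list(parse_descriptive_clone("Normal male"),
                   parse_descriptive_clone("Normal female"))
    } else {
      pops <- list(parse_descriptive_clone(body))
    }
    dialect <- "descriptive"
  } else {
    clones <- strsplit(body, "/", fixed = TRUE)[[1]]
    pops <- lapply(clones, parse_structured_clone, strict = strict)
    dialect <- "structured"
  }
  structure(
    list(populations = pops, cp = cp, has_prefix = has_prefix,
         dialect = dialect, normalized = body, raw = norm),
    class = "icp_call"
  )
}

#' Render a parsed icp call back to text
#'
#' Inverse of [parse_icp_string()] on canonical forms: structured clones are
#' re-rendered from their fields; descriptive clones reproduce their
#' normalized source text.
#'
#' @param call An `icp_call`.
#' @return Character string.
#' @export
render_icp_call <- function(call) {
  if (identical(call$dialect, "descriptive")) {
    body <- call$normalized
  } else {
    body <- paste(vapply(call$populations, render_karyotype, character(1)),
                  collapse = "/")
  }
  if (call$has_prefix) body <- paste0("icp.", body)
  if (!is.na(call$cp)) body <- paste0(body, "[cp", call$cp, "]")
  body
}

#' @export
print.icp_call <- function(x, ...) {
  cat("<icp_call> ", render_icp_call(x), "\n", sep = "")
  invisible(x)
}

clone_is_normal <- function(spec) {
  if (length(spec$gains) || length(spec$losses) || length(spec$events)) {
    return(FALSE)
  }
  if (spec$base_ploidy != 2L) return(FALSE)
  if (length(spec$annotations)) return(FALSE)
  if (!is.na(spec$count) && spec$count != 46L) return(FALSE)
  alts <- spec$sex_alternatives
  if (length(alts) == 1L && is.na(alts)) return(TRUE)   # sex unstated
  if (length(alts) == 1L && !nzchar(alts)) {
    # descriptive clone with empty complement, only sex alternatives matter
    return(TRUE)
  }
  all(alts[nzchar(alts)] %in% c("XX", "XY"))
}

#' Classify a result string as normal or abnormal
#'
#' A call is normal only when it is a single population that is exactly
#' 46,XX or 46,XY (or a plain "Normal") with no gains, losses, structural
#' events or mosaic annotations; everything else — including two-population
#' calls such as a male/female admixture — is abnormal.
#'
#' @param text Result string in either supported dialect.
#' @return Logical: TRUE when abnormal.
#' @export
classify_abnormal <- function(text) {
  call <- if (inherits(text, "icp_call")) text else parse_icp_string(text)
  if (length(call$populations) > 1L) return(TRUE)
  !clone_is_normal(call$populations[[1]])
}

event_class_key <- function(ev) {
  switch(ev$kind,
    TERMINAL_DELETION = paste("DEL", ev$chromosomes[1], ev$arms[1] %||% "?"),
    ROBERTSONIAN = paste("ROB", paste(ev$chromosomes, collapse = ";"),
                         ev$extra_copy_of %||% "balanced"),
    UNBALANCED_DER = paste("DER", paste(ev$chromosomes, collapse = ";"),
                           paste(ifelse(is.na(ev$arms), "?", ev$arms),
                                 collapse = ";")),
    RECIPROCAL_TRANSLOCATION = paste("T", paste(ev$chromosomes, collapse = ";"),
                                     paste(ifelse(is.na(ev$arms), "?", ev$arms),
                                           collapse = ";"))
  )
}

sex_compatible <- function(a, b) {
  aa <- a$sex_alternatives; bb <- b$sex_alternatives
  if ((length(aa) == 1L && is.na(aa)) || (length(bb) == 1L && is.na(bb))) {
    return(TRUE)                       # descriptive clone with unstated sex
  }
  aa <- aa[nzchar(aa)]; bb <- bb[nzchar(bb)]
  if (!length(aa) || !length(bb)) return(TRUE)
  length(intersect(aa, bb)) > 0L
}

clone_same_class <- function(a, b) {
  if (a$base_ploidy != b$base_ploidy) return(FALSE)
  if (!identical(sort(a$gains), sort(b$gains))) return(FALSE)
  if (!identical(sort(a$losses), sort(b$losses))) return(FALSE)
  ka <- sort(vapply(a$events, event_class_key, character(1)))
  kb <- sort(vapply(b$events, event_class_key, character(1)))
  if (!identical(ka, kb)) return(FALSE)
  sex_compatible(a, b)
}

#' Compare two result strings as karyotype classes
#'
#' Two strings belong to the same class when their populations agree on
#' ploidy, gain/loss multisets, structural events (kind, chromosomes and
#' arms; band text such as "q10" vs unknown "?" breakpoints is not compared)
#' and on a compatible sex complement ("XX or XY" matches either). The
#' leading chromosome count and any "[cpN]" suffix are not compared.
#'
#' @param a,b Result strings or `icp_call` objects.
#' @return Logical.
#' @export
same_karyotype_class <- function(a, b) {
  pa <- if (inherits(a, "icp_call")) a else parse_icp_string(a)
  pb <- if (inherits(b, "icp_call")) b else parse_icp_string(b)
  if (length(pa$populations) != length(pb$populations)) return(FALSE)
  all(vapply(seq_along(pa$populations), function(i) {
    clone_same_class(pa$populations[[i]], pb$populations[[i]])
  }, logical(1)))
}
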