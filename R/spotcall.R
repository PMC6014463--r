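# Per-cell signal extraction: single-linkage clustering of spots into
# distinct signals and multi-color fusion (juxtaposition) events.

empty_cell_pattern <- function(cell_id = NA_integer_) {
  structure(
    list(cell_id = cell_id,
         color_counts = stats::setNames(rep(0L, length(ICP_COLORS)),
                                        ICP_COLORS),
         fusions = list(),
         clusters = data.frame(cluster = integer(0), x = numeric(0),
                               y = numeric(0), colors = character(0),
                               stringsAsFactors = FALSE)),
    class = "icp_cell_pattern"
  )
}

#' Extract a cell's signal pattern from its spots
#'
#' Clusters are the connected components of the graph joining spots at
#' distance <= `fusion_radius` (single linkage; ties at exactly the radius
#' are joined). Same-color spots in one component count as a single signal
#' of that color — this is what re-merges split signals — and a component
#' whose spots carry two or more distinct colors is one fusion event.
#'
#' @param spots Data frame with columns `color`, `x`, `y` (the spots of one
#'   cell in one hybridization); zero rows allowed.
#' @param fusion_radius Juxtaposition distance (> 0).
#' @param cell_id Optional cell identifier carried into the result.
#' @return An `icp_cell_pattern`: `color_counts` (components containing each
#'   color), `fusions` (list of sorted color vectors, one per multi-color
#'   component) and `clusters` (one row per component with centroid and a
#'   "+"-joined sorted color list).
#' @export
extract_cell_pattern <- function(spots, fusion_radius, cell_id = NA_integer_) {
  if (!is.numeric(fusion_radius) || fusion_radius <= 0) {
    stop("fusion_radius must be a positive length")
  }
  n <- nrow(spots)
  if (is.null(n) || n == 0L) return(empty_cell_pattern(cell_id))
  bad <- setdiff(unique(spots$color), ICP_COLORS)
  if (length(bad)) stop("unknown spot color(s): ", paste(bad, collapse = ", "))

  if (n == 1L) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(cbind(spots$x, spots$y)),
                        method = "single")
    grp <- stats::cutree(hc, h = fusion_radius)
  }
  ids <- sort(unique(grp))
  counts <- stats::setNames(rep(0L, length(ICP_COLORS)), ICP_COLORS)
  fusions <- list()
  clusters <- data.frame(cluster = ids, x = NA_real_, y = NA_real_,
                         colors = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sel <- grp == ids[i]
    cols <- sort(unique(spots$color[sel]))
    counts[cols] <- counts[cols] + 1L
    if (length(cols) >= 2L) fusions <- c(fusions, list(cols))
    clusters$x[i] <- mean(spots$x[sel])
    clusters$y[i] <- mean(spots$y[sel])
    clusters$colors[i] <- paste(cols, collapse = "+")
  }
  structure(
    list(cell_id = cell_id, color_counts = counts, fusions = fusions,
         clusters = clusters),
    class = "icp_cell_pattern"
  )
}

#' @export
print.icp_cell_pattern <- function(x, ...) {
  nz <- x$color_counts[x$color_counts > 0]
  cat("<icp_cell_pattern> cell ", x$cell_id, ": ",
      paste(sprintf("%s:%d", names(nz), nz), collapse = " "), sep = "")
  if (length(x$fusions)) {
    cat(" | fusions: ",
        paste(vapply(x$fusions, paste, character(1), collapse = "+"),
              collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Extract patterns for every cell of a spot table
#'
#' @param spots Spot table (one hybridization) with columns `cell_id`,
#'   `color`, `x`, `y`.
#' @param fusion_radius Juxtaposition distance.
#' @param n_cells Number of cells analyzed; cells absent from the table
#'   (all signals undetected) yield empty patterns. Defaults to the largest
#'   cell id present.
#' @return List of `icp_cell_pattern`, one per cell id `1:n_cells`.
#' @export
extract_patterns <- function(spots, fusion_radius, n_cells = NULL) {
  if (is.null(n_cells)) {
    n_cells <- if (nrow(spots)) max(spots$cell_id) else 0L
  }
  lapply(seq_len(n_cells), function(cell) {
    extract_cell_pattern(spots[spots$cell_id == cell, , drop = FALSE],
                         fusion_radius, cell_id = cell)
  })
}

#' Serialize per-cell patterns to TSV
#'
#' One row per (cell, color) count plus one row per fusion event, whose
#' color set is serialized as a sorted "+"-joined list in the `colors`
#' column.
#'
#' @param patterns List of `icp_cell_pattern`.
#' @param path Output path.
#' @export
write_pattern_tsv <- function(patterns, path) {
  rows <- lapply(patterns, function(p) {
    counts <- data.frame(cell_id = p$cell_id, record = "count",
                         colors = names(p$color_counts),
                         value = as.integer(p$color_counts),
                         stringsAsFactors = FALSE)
    if (length(p$fusions)) {
      fus <- data.frame(cell_id = p$cell_id, record = "fusion",
                        colors = vapply(p$fusions, paste, character(1),
                                        collapse = "+"),
                        value = 1L, stringsAsFactors = FALSE)
      rbind(counts, fus)
    } else counts
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
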