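# Diagnostic plotting: one nucleus with its detected spots.

R_PLOT_COLORS <- c(AQUA = "cyan3", GREEN = "green3", YELLOW = "gold",
                   RED = "red2", FARRED = "darkred")

#' Plot the spots of one simulated or observed cell
#'
#' Draws the unit-disk nucleus outline and the cell's spots in their
#' fluorophore colors; useful for eyeballing territory placement, fusions
#' and displaced signals.
#'
#' @param spots Spot table (columns `color`, `x`, `y`, optionally
#'   `cell_id`).
#' @param cell Cell id to plot when `spots` holds several cells.
#' @param fusion_radius Optional radius; when given, circles of that
#'   radius are drawn around each spot so juxtapositions are visible.
#' @param main Plot title.
#' @export
plot_cell_spots <- function(spots, cell = NULL, fusion_radius = NULL,
                            main = NULL) {
  if (!is.null(cell) && "cell_id" %in% names(spots)) {
    spots <- spots[spots$cell_id == cell, , drop = FALSE]
  }
  theta <- seq(0, 2 * pi, length.out = 200)
  plot(cos(theta), sin(theta), type = "l", asp = 1, xlab = "", ylab = "",
       axes = FALSE, col = "grey50",
       main = main %||% paste0("cell", if (!is.null(cell)) paste0(" ", cell)))
  graphics::points(spots$x, spots$y, pch = 19, cex = 1.2,
                   col = R_PLOT_COLORS[spots$color])
  if (!is.null(fusion_radius)) {
    for (i in seq_len(nrow(spots))) {
      graphics::lines(spots$x[i] + fusion_radius * cos(theta),
                      spots$y[i] + fusion_radius * sin(theta),
                      col = "grey80", lty = 3)
    }
  }
  invisible(spots)
}
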