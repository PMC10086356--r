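#' Plot a slide's cells colored by phenotype
#'
#' Quick base-graphics overview of one slide: layer boundaries as
#' horizontal lines, excluded polygons outlined, cells colored by the
#' requested phenotype column.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param geometry a [layer_geometry()].
#' @param color_by column of `cells` to color by.
#' @param cex point size.
#' @return Invisibly, the color legend (named vector).
#' @export
plot_slide <- function(cells, geometry, color_by = "phenotype_adaptive",
                       cex = 0.2) {
  stopifnot(inherits(geometry, "layer_geometry"))
  lab <- if (color_by %in% names(cells)) cells[[color_by]]
         else rep("cell", nrow(cells))
  levs <- sort(unique(lab))
  pal <- grDevices::hcl.colors(max(3L, length(levs)), "Dark 3")[
    seq_along(levs)]
  names(pal) <- levs
  graphics::plot(NA, xlim = c(0, geometry$width_um),
                 ylim = c(0, geometry$height_um), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = cells$slide_id[1])
  graphics::points(cells$x_um, cells$y_um, col = pal[lab], pch = 16,
                   cex = cex)
  graphics::abline(h = c(geometry$y_intima_media,
                         geometry$y_media_adventitia), lty = 2)
  for (ex in geometry$excluded)
    graphics::polygon(ex$poly, border = "red", lty = 3)
  graphics::legend("topright", legend = levs, col = pal, pch = 16,
                   cex = 0.6, bg = "white")
  invisible(pal)
}
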