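#' Five-bin LD color scale
#'
#' LD values are binned into the five intervals (0,0.2], (0.2,0.4],
#' (0.4,0.6], (0.6,0.8], (0.8,1.0]; a value of 0 maps to the first bin.
#' Arguments are named after the bin upper bounds so a scale can be respecified
#' bin-by-bin (`color02` colors values up to 0.2, ... `color10` up to 1.0).
#'
#' @param color02,color04,color06,color08,color10 colors for the five bins.
#' @return An object of class `ld_color_scale`.
#' @export
ld_color_scale <- function(color02 = "#FEE5D9", color04 = "#FCAE91",
                           color06 = "#FB6A4A", color08 = "#DE2D26",
                           color10 = "#A50F15") {
  colors <- c(color02, color04, color06, color08, color10)
  stopifnot(length(colors) == 5L)
  structure(list(bounds = c(0.2, 0.4, 0.6, 0.8, 1.0), colors = colors),
            class = "ld_color_scale")
}

#' Map LD values to scale colors
#'
#' Returns the color of the first bin whose upper bound is at least the
#' value; 0 maps to the first bin, `NA` to `na_color`.
#'
#' @param value LD values in \[0, 1\] (NA allowed).
#' @param scale an [ld_color_scale].
#' @param na_color color for missing/failed pairs.
#' @return Character vector of colors.
#' @export
ld_color <- function(value, scale = ld_color_scale(), na_color = "gray85") {
  if (any(!is.na(value) & (value < 0 | value > 1)))
    usage_error("LD values must lie in [0, 1]")
  bin <- 1L + findInterval(value, scale$bounds[-5L], left.open = TRUE)
  out <- scale$colors[bin]
  out[is.na(value)] <- na_color
  out
}

#' Assemble plot styling
#'
#' @param scale an [ld_color_scale] for LD bins and lead-SNP coloring.
#' @param na_color color for pairs/markers with no LD value.
#' @param leadsnp_size size multiplier for the lead-SNP glyph (default 1).
#' @param lead_color,lead_pch lead-SNP glyph style.
#' @param point_pch,point_cex base scatter glyph.
#' @param highlight optional data.frame of highlight rows: a `marker` column
#'   (name) or `chrom`+`pos` columns, plus optional `pch`, `color`, `size`.
#' @param link2gene,link2LD optional marker-name vectors overriding which
#'   markers get scatter-to-gene and gene-to-LD linking segments (default:
#'   the significant set for both).
#' @return An object of class `plot_style`.
#' @export
plot_style <- function(scale = ld_color_scale(), na_color = "gray85",
                       leadsnp_size = 1, lead_color = "red3", lead_pch = 18,
                       point_pch = 16, point_cex = 0.8,
                       highlight = NULL, link2gene = NULL, link2LD = NULL) {
  if (leadsnp_size <= 0) usage_error("leadsnp_size must be > 0")
  structure(list(scale = scale, na_color = na_color,
                 leadsnp_size = leadsnp_size, lead_color = lead_color,
                 lead_pch = lead_pch, point_pch = point_pch,
                 point_cex = point_cex, highlight = highlight,
                 link2gene = link2gene, link2LD = link2LD),
            class = "plot_style")
}

#' Read a marker highlight table
#'
#' Delimited file with a `marker` column or `chrom` and `pos` columns, plus
#' optional `pch`, `color`, `size` columns.
#'
#' @param path path to the file.
#' @return A data.frame usable as `highlight` in [plot_style].
#' @export
read_highlight <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read highlight file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!("marker" %in% names(df)) && !all(c("chrom", "pos") %in% names(df)))
    format_error("highlight file needs a 'marker' column or 'chrom'+'pos' columns")
  df
}
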