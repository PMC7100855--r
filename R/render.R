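# Rendering: draws a figure_spec with base graphics onto a device chosen by
# the output file's extension. No layout decisions are made here.

open_device <- function(out, width = 9, height = 8, res = 150) {
  ext <- tolower(tools::file_ext(out))
  dir <- dirname(out)
  # the png device defers file creation to first plot; check writability now
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    io_error(sprintf("cannot write to output directory: %s", dir))
  ok <- tryCatch({
    switch(ext,
      png = grDevices::png(out, width = width, height = height,
                           units = "in", res = res),
      svg = grDevices::svg(out, width = width, height = height),
      pdf = grDevices::pdf(out, width = width, height = height),
      usage_error(sprintf("unsupported image extension '.%s' (png/svg/pdf)", ext)))
    TRUE
  }, error = function(e) {
    if (inherits(e, "ldassoc_usage_error")) stop(e)
    FALSE
  })
  if (!ok) io_error(sprintf("cannot open output device for: %s", out))
}

draw_figure <- function(spec) {
  layers <- spec$layers
  y_bottom <- min(layers$y_lo, na.rm = TRUE)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.12, 1.04), ylim = c(y_bottom - 0.03, 1.07))

  mk <- spec$markers
  sc_lo <- layers$y_lo[layers$layer == "scatter"]
  sc_hi <- layers$y_hi[layers$layer == "scatter"]
  g_lo <- layers$y_lo[layers$layer == "gene"]
  g_hi <- layers$y_hi[layers$layer == "gene"]

  # linking lines go underneath the points
  if (nrow(spec$links) > 0)
    graphics::segments(spec$links$x0, spec$links$y0, spec$links$x1,
                       spec$links$y1, col = "gray55", lwd = 0.8)

  # scatter layer: y axis, threshold line, points
  ticks <- pretty(c(0, spec$ymax), n = 5)
  ticks <- ticks[ticks <= spec$ymax]
  ty <- sc_lo + (ticks / spec$ymax) * (sc_hi - sc_lo)
  graphics::segments(-0.02, sc_lo, -0.02, sc_hi)
  graphics::segments(-0.03, ty, -0.02, ty)
  graphics::text(-0.04, ty, labels = ticks, cex = 0.7, adj = 1)
  graphics::text(-0.10, (sc_lo + sc_hi) / 2,
                 labels = expression(-log[10](italic(P))), srt = 90, cex = 0.9)
  if (!is.null(spec$threshold)) {
    yt <- sc_lo + (spec$threshold / spec$ymax) * (sc_hi - sc_lo)
    graphics::segments(0, yt, 1, yt, lty = 2, col = "gray30")
  }
  graphics::points(mk$x, mk$y, pch = mk$pch, col = mk$color, cex = mk$cex)
  if (!is.null(spec$labels))
    graphics::text(spec$labels$x, spec$labels$y, spec$labels$text,
                   cex = 0.7, font = 3)

  # genomic x axis between scatter and gene track
  span <- spec$region$right - spec$region$left
  gx <- pretty(c(spec$region$left, spec$region$right), n = 6)
  gx <- gx[gx >= spec$region$left & gx <= spec$region$right]
  gxx <- (gx - spec$region$left) / span
  graphics::segments(0, sc_lo - 0.015, 1, sc_lo - 0.015, col = "gray50")
  graphics::segments(gxx, sc_lo - 0.022, gxx, sc_lo - 0.015, col = "gray50")
  graphics::text(gxx, sc_lo - 0.035, labels = sprintf("%.3f Mb", gx / 1e6),
                 cex = 0.6, col = "gray30")

  # gene / transcript track
  mid <- (g_lo + g_hi) / 2
  if (!is.null(spec$transcript)) {
    tr <- spec$transcript
    graphics::segments(tr$x0, mid, tr$x1, mid, col = "gray40")
    if (!is.null(tr$introns) && nrow(tr$introns) > 0)
      graphics::segments(tr$introns$x0, mid, tr$introns$x1, mid, col = "gray40")
    b <- tr$boxes
    half <- ifelse(b$kind == "CDS", 0.45, ifelse(b$thin, 0.18, 0.32)) *
      (g_hi - g_lo) / 2
    fill <- c(exon = "steelblue3", CDS = "steelblue4",
              five_prime_UTR = "skyblue2", three_prime_UTR = "skyblue2")[b$kind]
    graphics::rect(b$x0, mid - half, b$x1, mid + half, col = fill, border = NA)
    ax <- if (tr$strand == "+") c(tr$x1, min(1, tr$x1 + 0.02))
          else c(tr$x0, max(0, tr$x0 - 0.02))
    graphics::arrows(ax[1L], mid, ax[2L], mid, length = 0.06, col = "gray40")
    graphics::text((tr$x0 + tr$x1) / 2, g_hi + 0.012, tr$id,
                   cex = 0.7, font = 3)
  } else if (!is.null(spec$genes) && nrow(spec$genes) > 0) {
    g <- spec$genes
    nlane <- max(g$lane)
    ylane <- g_lo + (g$lane - 0.5) / nlane * (g_hi - g_lo)
    graphics::arrows(ifelse(g$strand == "+", g$x0, g$x1), ylane,
                     ifelse(g$strand == "+", g$x1, g$x0), ylane,
                     length = 0.05, lwd = 1.6, col = "darkgreen")
    if (nrow(g) <= 12)
      graphics::text((g$x0 + g$x1) / 2, ylane + 0.012, g$gene_id,
                     cex = 0.55, font = 3, col = "darkgreen")
  }

  # triangle LD heatmap: one vectorized polygon call
  if (!is.null(spec$ld)) {
    d <- spec$ld$diamonds
    n <- spec$ld$n
    tc <- triangle_coords(d$i, d$j, n, y0 = 0)
    # index units -> normalized: x_norm = (x_idx + 0.5)/n, y shrinks by 1/n
    px <- (tc$x + 0.5) / n
    py <- spec$ld$y0 + tc$y / n
    xs <- as.vector(t(cbind(px, NA)))
    ys <- as.vector(t(cbind(py, NA)))
    graphics::polygon(xs, ys, col = d$color, border = NA)
    # color-scale legend
    leg_y <- spec$ld$y0 - 0.01
    bins <- sprintf("(%.1f,%.1f]", c(0, 0.2, 0.4, 0.6, 0.8),
                    c(0.2, 0.4, 0.6, 0.8, 1))
    cols <- unique_scale_colors(d)
    graphics::rect(1.005, leg_y - (5:1) * 0.02, 1.025, leg_y - (4:0) * 0.02,
                   col = cols, border = "gray40")
    graphics::text(1.03, leg_y - (5:1) * 0.02 + 0.01, bins, cex = 0.5, adj = 0)
    graphics::text(1.005, leg_y + 0.012,
                   if (spec$measure == "r2") expression(r^2) else "|D'|",
                   cex = 0.7, adj = 0)
  }
  invisible(spec)
}

# recover the five bin colors actually used (falls back to defaults)
unique_scale_colors <- function(d) {
  sc <- ld_color_scale()
  cols <- sc$colors
  if (nrow(d) > 0 && any(!is.na(d$value))) {
    bin <- 1L + findInterval(d$value, sc$bounds[-5L], left.open = TRUE)
    for (b in 1:5) {
      hit <- which(!is.na(bin) & bin == b)
      if (length(hit) > 0) cols[b] <- d$color[hit[1L]]
    }
  }
  cols
}

#' Render a regional association figure
#'
#' Draws the three aligned layers — the \eqn{-\log_{10}(P)} scatter with the
#' lead SNP enlarged and labeled and points colored by LD with the lead, a
#' gene track with one arrowed line per gene (arrow at the 3' end encodes
#' strand), and the triangle LD heatmap — plus the significance threshold
#' line and linking lines, to an image file chosen by extension
#' (png/svg/pdf).
#'
#' @param scope a `plot_scope` from [resolve_region], with lead and
#'   significance resolved.
#' @param ld an `ld_matrix` for the triangle layer (may come from a
#'   different genotype panel than `lead_ld`).
#' @param lead_ld a `lead_ld` vector for scatter coloring (or NULL).
#' @param style a [plot_style].
#' @param out output image path (`.png`, `.svg`, or `.pdf`).
#' @param matched optional mapping from [match_markers] (cross-panel mode).
#' @param leadsnp color/label by lead SNP?
#' @return The `figure_spec` drawn, invisibly.
#' @export
render_regional <- function(scope, ld = NULL, lead_ld = NULL,
                            style = plot_style(), out, matched = NULL,
                            leadsnp = TRUE) {
  spec <- build_figure_spec(scope, ld, lead_ld, style, matched,
                            triangleLD = !is.null(ld), leadsnp = leadsnp)
  open_device(out)
  on.exit(grDevices::dev.off(), add = TRUE)
  draw_figure(spec)
  invisible(spec)
}

#' Render a single-gene association figure
#'
#' As [render_regional], but the middle track draws the transcript's feature
#' boxes to genomic scale — CDS as tall filled boxes, exons as mid-height
#' boxes, UTRs thinner, introns as connector lines. `triangleLD = FALSE`
#' suppresses the LD layer; `leadsnp = FALSE` suppresses lead-SNP coloring
#' and labeling.
#'
#' @param scope a `plot_scope` from [resolve_genic].
#' @param ld an `ld_matrix` (ignored when `triangleLD = FALSE`).
#' @param style a [plot_style].
#' @param out output image path.
#' @param triangleLD,leadsnp layer switches.
#' @param lead_ld optional `lead_ld` vector for scatter coloring.
#' @param matched optional cross-panel mapping.
#' @return The `figure_spec` drawn, invisibly.
#' @export
render_genic <- function(scope, ld = NULL, style = plot_style(), out,
                         triangleLD = TRUE, leadsnp = TRUE,
                         lead_ld = NULL, matched = NULL) {
  spec <- build_figure_spec(scope, ld, lead_ld, style, matched,
                            triangleLD = triangleLD, leadsnp = leadsnp)
  open_device(out)
  on.exit(grDevices::dev.off(), add = TRUE)
  draw_figure(spec)
  invisible(spec)
}
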