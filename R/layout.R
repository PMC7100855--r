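# Figure geometry. All layout is computed here, deterministically, into a
# figure_spec; rendering only draws what the spec contains. Coordinates are
# normalized: x in [0, 1] maps the genomic window (scatter and gene layers);
# the LD layer places markers at equal index spacing (Haploview convention),
# with the linking lines absorbing the genomic-to-index distortion.

#' Diamond cell of the triangle LD heatmap
#'
#' For marker pair (i, j), i < j, of an n-marker panel, the cell is a diamond
#' centered at x = (i + j)/2, y = y0 - (j - i)/2 in index units, with
#' half-diagonal 1/2; the cells tile the triangle without overlap.
#'
#' @param i,j 0-based marker indices, `0 <= i < j < n`.
#' @param n marker count.
#' @param y0 y of the triangle's top edge (index units).
#' @return A list with `center` (x, y) and `x`, `y`: the 4 vertex
#'   coordinates (right, top, left, bottom).
#' @export
triangle_coords <- function(i, j, n, y0 = 0) {
  if (any(i < 0 | j <= i | j >= n))
    usage_error("triangle_coords requires 0 <= i < j < n")
  cx <- (i + j) / 2
  cy <- y0 - (j - i) / 2
  list(center = cbind(x = cx, y = cy),
       x = cbind(cx + 0.5, cx, cx - 0.5, cx),
       y = cbind(cy, cy + 0.5, cy, cy - 0.5))
}

# greedy first-fit lane assignment for (possibly overlapping) gene spans
assign_lanes <- function(start, end, gap = 0) {
  ord <- order(start, end)
  lane <- integer(length(start))
  lane_end <- numeric(0)
  for (k in ord) {
    fit <- which(lane_end < start[k] - gap)
    if (length(fit) == 0) {
      lane_end <- c(lane_end, end[k])
      lane[k] <- length(lane_end)
    } else {
      lane[k] <- fit[1L]
      lane_end[fit[1L]] <- end[k]
    }
  }
  lane
}

# deterministic vertical label repulsion: fixed iteration count, no RNG
repel_labels <- function(x, y, width = 0.08, height = 0.035, iters = 30L) {
  n <- length(x)
  if (n < 2) return(y)
  for (it in seq_len(iters)) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (abs(x[a] - x[b]) < width && abs(y[a] - y[b]) < height) {
        push <- (height - abs(y[a] - y[b])) / 2
        if (y[a] <= y[b]) { y[a] <- y[a] - push; y[b] <- y[b] + push }
        else              { y[b] <- y[b] - push; y[a] <- y[a] + push }
      }
    }
  }
  y
}

#' Linking lines between the three layers
#'
#' For each selected marker, segment A drops from its scatter point to its
#' genomic x on the gene-track baseline; segment B continues from there to
#' the marker's index position on the LD triangle's top edge. By default the
#' significant set is linked; `link2gene`/`link2LD` in the style override the
#' segment-A/segment-B selections independently. Markers with no match in
#' the LD panel get segment A only.
#'
#' @param scope a `plot_scope` (with significance resolved).
#' @param layout a partially built `figure_spec` (markers and layer extents).
#' @param links list with elements `link2gene`, `link2LD` (marker-name
#'   vectors or NULL).
#' @param matched integer mapping from scope markers to LD-panel indices
#'   (NA = unmatched), as from [match_markers].
#' @return data.frame of segments: `marker`, `segment` ("A"/"B"), `x0`,
#'   `y0`, `x1`, `y1`.
#' @export
linking_lines <- function(scope, layout, links = list(), matched = NULL) {
  mk <- layout$markers
  pick <- function(sel) {
    if (is.null(sel)) return(mk$name %in% scope$significant)
    unknown <- setdiff(sel, mk$name)
    if (length(unknown) > 0)
      warning(sprintf("link selector(s) outside scope skipped: %s",
                      paste(unknown, collapse = ", ")))
    mk$name %in% sel
  }
  selA <- pick(links$link2gene)
  selB <- pick(links$link2LD)
  gene_top <- layout$layers$y_hi[layout$layers$layer == "gene"]
  gene_lo  <- layout$layers$y_lo[layout$layers$layer == "gene"]
  segs <- list()
  if (any(selA))
    segs$A <- data.frame(marker = mk$name[selA], segment = "A",
                         x0 = mk$x[selA], y0 = mk$y[selA],
                         x1 = mk$x[selA], y1 = gene_top)
  has_ld <- !is.null(layout$ld) && layout$ld$n >= 2
  if (has_ld && any(selB)) {
    idx <- if (is.null(matched)) {
      match(paste(mk$chrom, mk$pos), paste(layout$ld$markers$chrom,
                                           layout$ld$markers$pos))
    } else matched
    ok <- selB & !is.na(idx)
    if (any(ok)) {
      xb <- (idx[ok] - 1 + 0.5) / layout$ld$n   # index -> normalized x
      segs$B <- data.frame(marker = mk$name[ok], segment = "B",
                           x0 = mk$x[ok], y0 = gene_lo,
                           x1 = xb, y1 = layout$ld$y0)
    }
  }
  if (length(segs) == 0)
    return(data.frame(marker = character(), segment = character(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Compute the full figure geometry
#'
#' Resolves the three-layer layout (association scatter, gene/transcript
#' track, triangle LD heatmap), marker coordinates in every layer, diamond
#' cells with bin colors, linking polylines, and per-point styling. The
#' result is pure data: rendering it twice gives identical output.
#'
#' @param scope a `plot_scope` with lead and significance resolved (unless
#'   `leadsnp = FALSE`).
#' @param ld an `ld_matrix` for the triangle layer (or NULL).
#' @param lead_ld a `lead_ld` vector for coloring scatter points by LD with
#'   the lead SNP (or NULL).
#' @param style a [plot_style].
#' @param matched mapping of scope markers into the LD panel (from
#'   [match_markers]); defaults to exact (chrom, pos) matching.
#' @param triangleLD draw the LD triangle layer?
#' @param leadsnp color points by lead-SNP LD and mark/label the lead?
#' @return An object of class `figure_spec`.
#' @export
build_figure_spec <- function(scope, ld = NULL, lead_ld = NULL,
                              style = plot_style(), matched = NULL,
                              triangleLD = TRUE, leadsnp = TRUE) {
  region <- scope$region
  span <- region$right - region$left
  xg <- function(pos) (pos - region$left) / span

  have_ld <- triangleLD && !is.null(ld) && nrow(ld$markers) >= 2
  layers <- data.frame(layer = c("scatter", "gene", "ld"),
                       y_lo = c(0.60, 0.47, NA), y_hi = c(1.00, 0.57, 0.44))
  # scatter scale
  a <- scope$assoc
  lp <- neglog10(a$p)
  ymax <- max(lp, scope$threshold, 1) * 1.05
  sc_lo <- layers$y_lo[1L]; sc_hi <- layers$y_hi[1L]
  ysc <- function(v) sc_lo + (v / ymax) * (sc_hi - sc_lo)

  is_lead <- !is.null(scope$lead) & a$marker == if (!is.null(scope$lead))
    scope$lead$marker else ""
  mk <- data.frame(name = a$marker, chrom = a$chrom, pos = a$pos, p = a$p,
                   neglogp = lp, x = xg(a$pos), y = ysc(lp),
                   lead = is_lead, significant = a$marker %in% scope$significant)

  # point colors: LD with the lead (5-bin scale) when leadsnp is on
  mk$color <- "gray40"
  if (leadsnp && !is.null(lead_ld)) {
    key <- paste(mk$chrom, mk$pos)
    r2 <- lead_ld$r2[match(key, paste(lead_ld$chrom, lead_ld$pos))]
    mk$color <- ld_color(r2, style$scale, style$na_color)
  }
  mk$pch <- style$point_pch
  mk$cex <- style$point_cex
  if (leadsnp && any(mk$lead)) {
    mk$color[mk$lead] <- style$lead_color
    mk$pch[mk$lead] <- style$lead_pch
    mk$cex[mk$lead] <- style$point_cex * 1.6 * style$leadsnp_size
  }

  # highlight overrides (by name or exact chrom:pos)
  if (!is.null(style$highlight)) {
    h <- style$highlight
    hit <- if ("marker" %in% names(h)) match(h$marker, mk$name)
           else match(paste(h$chrom, h$pos), paste(mk$chrom, mk$pos))
    if (anyNA(hit))
      warning(sprintf("%d highlight selector(s) matched no scope marker",
                      sum(is.na(hit))))
    ok <- !is.na(hit)
    if ("pch" %in% names(h))   mk$pch[hit[ok]] <- h$pch[ok]
    if ("color" %in% names(h)) mk$color[hit[ok]] <- h$color[ok]
    if ("size" %in% names(h))  mk$cex[hit[ok]] <- style$point_cex * h$size[ok]
  }

  spec <- list(region = region, mode = scope$mode, layers = layers,
               markers = mk, threshold = scope$threshold,
               ymax = ymax, measure = if (!is.null(ld)) ld$measure else "r2")

  # gene / transcript track
  if (scope$mode == "genic" && !is.null(scope$transcript)) {
    tx <- scope$transcript
    f <- tx$features
    exons <- f[f$kind == "exon", , drop = FALSE]
    boxes <- data.frame(kind = f$kind,
                        x0 = pmax(0, xg(f$start - 0.5)),
                        x1 = pmin(1, xg(f$end + 0.5)),
                        thin = f$kind %in% c("five_prime_UTR", "three_prime_UTR"))
    introns <- NULL
    if (nrow(exons) >= 2) {
      e <- exons[order(exons$start), , drop = FALSE]
      introns <- data.frame(x0 = xg(e$end[-nrow(e)] + 0.5),
                            x1 = xg(e$start[-1L] - 0.5))
    }
    spec$transcript <- list(id = tx$transcript_id, strand = tx$strand,
                            x0 = max(0, xg(tx$start)), x1 = min(1, xg(tx$end)),
                            boxes = boxes, introns = introns)
  } else {
    g <- scope$genes
    if (nrow(g) > 0) {
      spec$genes <- data.frame(gene_id = g$gene_id, strand = g$strand,
                               x0 = pmax(0, xg(g$start)), x1 = pmin(1, xg(g$end)),
                               lane = assign_lanes(g$start, g$end,
                                                   gap = 0.01 * span))
    } else {
      spec$genes <- data.frame(gene_id = character(), strand = character(),
                               x0 = numeric(), x1 = numeric(), lane = integer())
    }
  }

  # triangle LD layer (equal index spacing)
  if (have_ld) {
    n <- nrow(ld$markers)
    y0 <- layers$y_hi[3L]
    depth <- (n - 1) / (2 * n)
    spec$layers$y_lo[3L] <- y0 - depth
    val <- ld$pairs[[if (ld$measure == "r2") "r2" else "Dprime"]]
    spec$ld <- list(
      n = n, y0 = y0,
      markers = ld$markers,
      top_x = (seq_len(n) - 1 + 0.5) / n,
      diamonds = data.frame(i = ld$pairs$i - 1L, j = ld$pairs$j - 1L,
                            value = val,
                            color = ld_color(val, style$scale, style$na_color)))
    # order isomorphism: index order must equal genomic order
    stopifnot(!is.unsorted(ld$markers$pos))
  } else {
    spec$layers <- layers[1:2, , drop = FALSE]
    spec$ld <- NULL
  }

  spec$links <- linking_lines(scope, spec,
                              links = list(link2gene = style$link2gene,
                                           link2LD = style$link2LD),
                              matched = matched)

  # labels: lead SNP plus highlighted markers with a label column
  lab <- NULL
  if (leadsnp && any(mk$lead))
    lab <- data.frame(text = mk$name[mk$lead], x = mk$x[mk$lead],
                      y = mk$y[mk$lead] + 0.03)
  if (!is.null(style$highlight) && "label" %in% names(style$highlight)) {
    h <- style$highlight
    hit <- match(h$marker, mk$name)
    ok <- !is.na(hit) & nzchar(h$label)
    if (any(ok))
      lab <- rbind(lab, data.frame(text = h$label[ok], x = mk$x[hit[ok]],
                                   y = mk$y[hit[ok]] + 0.03))
  }
  if (!is.null(lab)) {
    lab$y <- repel_labels(lab$x, lab$y)
    spec$labels <- lab
  }
  structure(spec, class = "figure_spec")
}

#' @export
print.figure_spec <- function(x, ...) {
  cat(sprintf("figure_spec [%s] %s:%s-%s: %d markers, %d link segments%s\n",
              x$mode, x$region$chrom,
              format(x$region$left, big.mark = ","),
              format(x$region$right, big.mark = ","),
              nrow(x$markers), nrow(x$links),
              if (!is.null(x$ld))
                sprintf(", LD triangle %d markers (%d cells)",
                        x$ld$n, nrow(x$ld$diamonds)) else ""))
  invisible(x)
}
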