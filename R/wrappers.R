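# End-to-end entry points: file paths (or already-loaded objects) in, image
# out. These orchestrate the readers, scope resolution, LD estimation and
# rendering, and emit a run report via message().

as_association <- function(x, column_map = NULL) {
  if (inherits(x, "association_table")) return(x)
  if (is.character(x)) {
    if (is.null(column_map)) return(read_association(x))
    return(read_association(x, column_map = column_map))
  }
  usage_error("association must be a path or an association_table")
}

as_annotation <- function(x) {
  if (inherits(x, "annotation_set")) return(x)
  if (is.character(x)) return(read_gtf(x))
  usage_error("gtf must be a path or an annotation_set")
}

as_genotypes <- function(x) {
  if (is.null(x) || inherits(x, "genotype_matrix")) return(x)
  if (is.character(x)) return(read_hapmap(x))
  usage_error("hapmap must be a path or a genotype_matrix")
}

# panel subset within the scope window (indices into gt markers)
panel_in_region <- function(gt, region) {
  which(gt$markers$chrom == region$chrom &
        gt$markers$pos >= region$left & gt$markers$pos <= region$right)
}

# shared scaffolding once a scope is resolved: lead, significance, LD
# panels, matching, rendering inputs
plot_pipeline <- function(scope, gt, gt_ld, threshold, lead_snp, measure,
                          leadsnp = TRUE) {
  scope <- find_lead(scope, lead_snp)
  scope <- filter_significant(scope, threshold)

  lead_ld <- NULL
  if (leadsnp) {
    li <- tryCatch(resolve_marker_ref(gt, scope$lead),
                   ldassoc_lookup_error = function(e) NULL)
    if (is.null(li)) {
      warning(sprintf("lead SNP %s:%d absent from the genotype panel; %s",
                      scope$lead$chrom, scope$lead$pos,
                      "scatter points will not be LD-colored"))
    } else {
      lead_ld <- lead_snp_ld(gt, scope$lead,
                             markers = panel_in_region(gt, scope$region))
    }
  }

  idx_ld <- panel_in_region(gt_ld, scope$region)
  ld <- NULL
  matched <- NULL
  if (length(idx_ld) >= 2) {
    sub <- gt_subset(gt_ld, idx_ld)
    ld <- ld_matrix(sub, measure = measure)
    matched <- match_markers(scope$assoc, sub)
  }
  list(scope = scope, ld = ld, lead_ld = lead_ld, matched = matched)
}

report_run <- function(gt, gt_ld, parts) {
  message(sprintf("markers: %d loaded (%d dropped at load) in genotype panel",
                  gt$report$n_retained, gt$report$n_dropped))
  if (!is.null(parts$ld))
    message(sprintf("LD: %d markers in window, %d pairs computed",
                    nrow(parts$ld$markers), nrow(parts$ld$pairs)))
  if (!is.null(parts$matched)) {
    nun <- attr(parts$matched, "n_unmatched")
    message(sprintf(
      "linking: %d association marker(s) unmatched in the LD panel%s",
      nun, if (nun > 0) " (their linking lines stop at the gene track)" else ""))
  }
  message(sprintf("scope: %d association markers, lead SNP %s, %d significant",
                  nrow(parts$scope$assoc), parts$scope$lead$marker,
                  length(parts$scope$significant)))
}

#' Regional association plot (scatter + gene arrows + LD triangle)
#'
#' One-call pipeline for a chromosome window: resolves the scope, picks the
#' lead SNP, computes lead-SNP LD from the association genotype panel and the
#' triangle LD matrix from `hapmap_ld` (defaulting to the same panel), and
#' renders the aligned three-layer figure with linking lines.
#'
#' @param chr,left,right chromosome and window bounds (bp, closed interval).
#' @param gtf annotation: a GTF path or an [annotation_set].
#' @param association a delimited results path or an `association_table`.
#' @param hapmap genotype panel backing the association: HapMap path or
#'   [genotype_matrix].
#' @param hapmap_ld optional second genotype panel for the triangle LD layer.
#' @param threshold genome-wide significance cutoff on the
#'   \eqn{-\log_{10}(p)} scale.
#' @param lead_snp optional user-designated lead marker (name or
#'   `list(chrom=, pos=)`); default: most significant in window.
#' @param out output image path (.png/.svg/.pdf).
#' @param measure `"r2"` or `"Dprime"` for the triangle layer.
#' @param style a [plot_style] (colors, highlights, link selections, lead
#'   glyph size).
#' @param column_map optional association column remapping (see
#'   [read_association]).
#' @return Invisibly, a list with `scope`, `ld`, `lead_ld`, `matched`, and
#'   the rendered `spec`.
#' @export
regional_plot <- function(chr, left, right, gtf, association, hapmap,
                          hapmap_ld = NULL, threshold = 5, lead_snp = NULL,
                          out, measure = c("r2", "Dprime"),
                          style = plot_style(), column_map = NULL) {
  measure <- match.arg(measure)
  assoc <- as_association(association, column_map)
  ann <- as_annotation(gtf)
  gt <- as_genotypes(hapmap)
  gt_ld <- if (is.null(hapmap_ld)) gt else as_genotypes(hapmap_ld)

  scope <- resolve_region(assoc, ann, region_spec(chr, left, right))
  parts <- plot_pipeline(scope, gt, gt_ld, threshold, lead_snp, measure)
  report_run(gt, gt_ld, parts)
  spec <- render_regional(parts$scope, parts$ld, parts$lead_ld, style, out,
                          matched = parts$matched)
  invisible(c(parts, list(spec = spec)))
}

#' Single-gene association plot (scatter + transcript structure + LD)
#'
#' As [regional_plot] but the window is a transcript span plus strand-aware
#' flanks, and the middle track draws the transcript's exon/CDS/UTR
#' structure.
#'
#' @param transcript transcript id present in the annotation.
#' @param up,down flank lengths in bp (5' and 3' of the transcript,
#'   strand-aware).
#' @param leadsnp color/label scatter points by LD with the lead SNP?
#' @param triangleLD draw the LD triangle layer?
#' @inheritParams regional_plot
#' @return Invisibly, a list with `scope`, `ld`, `lead_ld`, `matched`,
#'   `spec`.
#' @export
genic_plot <- function(transcript, gtf, association, hapmap,
                       hapmap_ld = NULL, threshold = 5, up = 0, down = 0,
                       leadsnp = TRUE, triangleLD = TRUE, lead_snp = NULL,
                       out, measure = c("r2", "Dprime"),
                       style = plot_style(), column_map = NULL) {
  measure <- match.arg(measure)
  assoc <- as_association(association, column_map)
  ann <- as_annotation(gtf)
  gt <- as_genotypes(hapmap)
  gt_ld <- if (is.null(hapmap_ld)) gt else as_genotypes(hapmap_ld)

  scope <- resolve_genic(assoc, ann, transcript, up = up, down = down)
  parts <- plot_pipeline(scope, gt, gt_ld, threshold, lead_snp, measure,
                         leadsnp = leadsnp)
  report_run(gt, gt_ld, parts)
  spec <- render_genic(parts$scope, if (triangleLD) parts$ld else NULL,
                       style, out, triangleLD = triangleLD,
                       leadsnp = leadsnp, lead_ld = parts$lead_ld,
                       matched = parts$matched)
  invisible(c(parts, list(spec = spec)))
}
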