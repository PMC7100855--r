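#' Define a genomic region
#'
#' @param chrom chromosome name.
#' @param left,right 1-based window bounds in basepairs; closed interval,
#'   `left < right`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(chrom, left, right) {
  left <- as.numeric(left); right <- as.numeric(right)
  if (!(left < right)) usage_error("region: left must be < right")
  if (left < 1) usage_error("region: left must be >= 1")
  structure(list(chrom = as.character(chrom), left = left, right = right),
            class = "region_spec")
}

# gene rows of an annotation set whose span overlaps [left, right] by >= 1 bp
genes_in_region <- function(ann, region) {
  g <- ann$genes
  hit <- g$chrom == region$chrom & g$start <= region$right & g$end >= region$left
  g[hit, , drop = FALSE]
}

new_plot_scope <- function(region, assoc, genes, transcripts, mode,
                           transcript = NULL) {
  assoc <- assoc[order(assoc$pos), , drop = FALSE]
  rownames(assoc) <- NULL
  structure(list(region = region, assoc = assoc, genes = genes,
                 transcripts = transcripts, mode = mode,
                 transcript = transcript,
                 lead = NULL, significant = character(), threshold = NULL),
            class = "plot_scope")
}

#' @export
print.plot_scope <- function(x, ...) {
  cat(sprintf("plot_scope [%s] %s:%s-%s\n", x$mode, x$region$chrom,
              format(x$region$left, big.mark = ","),
              format(x$region$right, big.mark = ",")))
  cat(sprintf("  %d association markers, %d genes, %d transcripts\n",
              nrow(x$assoc), nrow(x$genes), length(x$transcripts)))
  if (!is.null(x$lead))
    cat(sprintf("  lead SNP: %s (%s:%d, p=%.3g)\n", x$lead$marker,
                x$lead$chrom, x$lead$pos, x$lead$p))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold -log10(p) >= %g: %d significant\n",
                x$threshold, length(x$significant)))
  invisible(x)
}

#' Resolve a regional plotting scope
#'
#' Restricts an association table to a chromosome window (closed interval,
#' boundary markers included) and collects the gene models overlapping the
#' window by at least 1 bp.
#'
#' @param assoc an `association_table`.
#' @param ann an [annotation_set].
#' @param region a [region_spec].
#' @return A `plot_scope` (lead SNP and significance set unset; see
#'   [find_lead] and [filter_significant]).
#' @export
resolve_region <- function(assoc, ann, region) {
  stopifnot(inherits(region, "region_spec"))
  keep <- assoc$chrom == region$chrom &
    assoc$pos >= region$left & assoc$pos <= region$right
  if (!any(keep))
    scope_error(sprintf(
      "no association markers in %s:%s-%s; widen the window",
      region$chrom, format(region$left, big.mark = ","),
      format(region$right, big.mark = ",")))
  genes <- genes_in_region(ann, region)
  txids <- unlist(genes$transcript_ids, use.names = FALSE)
  new_plot_scope(region, assoc[keep, , drop = FALSE], genes,
                 ann$transcripts[txids], mode = "regional")
}

#' Resolve a single-gene (transcript) plotting scope
#'
#' The window is the transcript span extended by `up` basepairs on its 5'
#' side and `down` on its 3' side, strand-aware: for a minus-strand
#' transcript `up` extends the genomic right edge. The transcript's feature
#' models are kept for the gene-structure layer.
#'
#' @param assoc an `association_table`.
#' @param ann an [annotation_set].
#' @param transcript_id transcript identifier present in `ann`.
#' @param up,down non-negative flank lengths in basepairs (default 0).
#' @return A `plot_scope` with `mode = "genic"`.
#' @export
resolve_genic <- function(assoc, ann, transcript_id, up = 0, down = 0) {
  if (up < 0 || down < 0) usage_error("up/down flanks must be >= 0")
  tx <- ann$transcripts[[transcript_id]]
  if (is.null(tx)) {
    cand <- names(ann$transcripts)
    near <- cand[order(utils::adist(transcript_id, cand))]
    lookup_error(sprintf("unknown transcript '%s'; nearest: %s", transcript_id,
                         paste(utils::head(near, 5L), collapse = ", ")))
  }
  if (tx$strand == "+") {
    region <- region_spec(tx$chrom, max(1, tx$start - up), tx$end + down)
  } else {
    region <- region_spec(tx$chrom, max(1, tx$start - down), tx$end + up)
  }
  keep <- assoc$chrom == region$chrom &
    assoc$pos >= region$left & assoc$pos <= region$right
  if (!any(keep))
    scope_error(sprintf("no association markers in the %s window of %s",
                        tx$chrom, transcript_id))
  genes <- genes_in_region(ann, region)
  scope <- new_plot_scope(region, assoc[keep, , drop = FALSE], genes,
                          ann$transcripts[transcript_id], mode = "genic",
                          transcript = tx)
  scope
}

#' Minus log10 of a p-value
#'
#' @param p probability in (0, 1].
#' @return \eqn{-\log_{10}(p) \ge 0}.
#' @export
neglog10 <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) usage_error("p must be in (0, 1]")
  -log10(p)
}

#' Pick the lead SNP of a scope
#'
#' The user-specified marker if given (must be in scope), else the most
#' strongly associated marker (smallest p). Ties break to the smallest
#' position, then to the lexically smallest name, so plots are deterministic.
#'
#' @param scope a `plot_scope`.
#' @param user_snp optional marker name, or a list with `chrom` and `pos`.
#' @return The scope updated with `$lead` set to the lead association row.
#' @export
find_lead <- function(scope, user_snp = NULL) {
  a <- scope$assoc
  if (nrow(a) == 0) scope_error("scope has no association markers")
  if (!is.null(user_snp)) {
    if (is.character(user_snp)) {
      i <- which(a$marker == user_snp)
      if (length(i) == 0)
        lookup_error(sprintf("lead marker '%s' not in scope", user_snp))
    } else {
      i <- which(a$chrom == as.character(user_snp$chrom) &
                 a$pos == as.integer(user_snp$pos))
      if (length(i) == 0)
        lookup_error(sprintf("lead marker at %s:%s not in scope",
                             user_snp$chrom, user_snp$pos))
    }
    i <- i[1L]
  } else {
    i <- order(a$p, a$pos, a$marker)[1L]
  }
  scope$lead <- a[i, , drop = FALSE]
  scope
}

#' Select the significant marker set
#'
#' Markers whose association reaches \eqn{-\log_{10}(p) \ge} `threshold`
#' (boundary inclusive). These markers get linking lines by default.
#'
#' @param scope a `plot_scope`.
#' @param threshold non-negative cutoff on the \eqn{-\log_{10}} scale.
#' @return The scope updated with `$significant` (marker names) and
#'   `$threshold`.
#' @export
filter_significant <- function(scope, threshold) {
  if (threshold < 0) usage_error("threshold must be >= 0")
  lp <- neglog10(scope$assoc$p)
  scope$significant <- scope$assoc$marker[lp >= threshold]
  scope$threshold <- threshold
  scope
}
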