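GTF_KINDS <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

# normalize the many spellings of UTR feature types found in GTF files
normalize_kind <- function(type) {
  k <- as.character(type)
  k[k %in% c("five_prime_utr", "5UTR", "5'UTR", "five_prime_UTR")] <- "five_prime_UTR"
  k[k %in% c("three_prime_utr", "3UTR", "3'UTR", "three_prime_UTR")] <- "three_prime_UTR"
  k
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,chrom,strand transcript identity; strand is
#'   `"+"` or `"-"`.
#' @param features data.frame with columns `kind` (one of exon, CDS,
#'   five_prime_UTR, three_prime_UTR), `start`, `end` (1-based, closed).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, features) {
  stopifnot(strand %in% c("+", "-"),
            all(features$start <= features$end),
            all(features$kind %in% GTF_KINDS))
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand,
                 start = min(features$start), end = max(features$end),
                 features = features),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%d-%d (%s), %d features\n",
              x$transcript_id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$features)))
  invisible(x)
}

#' Construct an annotation set
#'
#' @param transcripts named list of [transcript_model] objects, keyed by
#'   transcript id.
#' @return An object of class `annotation_set` with a `$genes` table (gene
#'   span = union of its transcripts' spans) and a `$transcripts` list.
#' @export
annotation_set <- function(transcripts = list()) {
  if (length(transcripts) == 0) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(), strand = character())
    genes$transcript_ids <- list()
    return(structure(list(transcripts = list(), genes = genes),
                     class = "annotation_set"))
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- do.call(rbind, lapply(split(seq_along(transcripts), gid), function(ii) {
    txs <- transcripts[ii]
    data.frame(gene_id = txs[[1L]]$gene_id, chrom = txs[[1L]]$chrom,
               start = min(vapply(txs, `[[`, 0, "start")),
               end = max(vapply(txs, `[[`, 0, "end")),
               strand = txs[[1L]]$strand)
  }))
  genes$transcript_ids <- lapply(split(names(transcripts), gid), identity)[genes$gene_id]
  genes <- genes[order_chrom_pos(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(transcripts = transcripts, genes = genes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d transcripts\n",
              nrow(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses a GTF2.2-style annotation via `rtracklayer::import` and keeps
#' exon/CDS/UTR features that carry both `gene_id` and `transcript_id`
#' attributes. Other feature kinds are ignored; exon/CDS/UTR rows lacking a
#' `transcript_id` are skipped with a warning. An empty file yields an empty
#' annotation set.
#'
#' @param path path to a GTF file.
#' @return An [annotation_set].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read GTF file: %s", path))
  lines <- tryCatch(readLines(path), error = function(e)
    io_error(sprintf("cannot read GTF file: %s (%s)", path, conditionMessage(e))))
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    return(annotation_set())
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"), error = function(e)
    format_error(sprintf("failed to parse GTF %s: %s", path, conditionMessage(e))))
  df <- as.data.frame(gr)
  df$kind <- normalize_kind(df$type)
  df <- df[df$kind %in% GTF_KINDS, , drop = FALSE]
  if (nrow(df) == 0) return(annotation_set())
  if (!"transcript_id" %in% names(df)) df$transcript_id <- NA_character_
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  skip <- is.na(df$transcript_id) | is.na(df$gene_id)
  if (any(skip)) {
    warning(sprintf(
      "skipped %d exon/CDS/UTR feature(s) lacking transcript_id/gene_id (first at %s:%d-%d)",
      sum(skip), df$seqnames[skip][1L], df$start[skip][1L], df$end[skip][1L]))
    df <- df[!skip, , drop = FALSE]
  }
  if (nrow(df) == 0) return(annotation_set())
  txs <- lapply(split(df, df$transcript_id), function(d) {
    feats <- data.frame(kind = d$kind, start = d$start, end = d$end)
    feats <- feats[order(feats$start, feats$end, feats$kind), , drop = FALSE]
    rownames(feats) <- NULL
    transcript_model(d$transcript_id[1L], d$gene_id[1L],
                     as.character(d$seqnames[1L]), as.character(d$strand[1L]),
                     feats)
  })
  annotation_set(txs)
}

#' Write an annotation set to a GTF file
#'
#' Emits one 9-column GTF line per transcript feature with `gene_id` and
#' `transcript_id` attributes. Used chiefly to materialize simulated gene
#' models for the file-based interface.
#'
#' @param ann an [annotation_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- unlist(lapply(ann$transcripts, function(tx) {
    sprintf('%s\tldassoc\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            tx$chrom, tx$features$kind, tx$features$start, tx$features$end,
            tx$strand, tx$gene_id, tx$transcript_id)
  }), use.names = FALSE)
  ok <- tryCatch({ writeLines(rows, path); TRUE }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write GTF file: %s", path))
  invisible(path)
}
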