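#' Read a GWAS association result table
#'
#' Reads a delimited text table of per-marker association results (the
#' delimiter is sniffed from the header line: tab, comma, or semicolon).
#' Column names default to the TASSEL convention (`Marker`, `Locus`, `Site`,
#' `p`) and can be remapped via `column_map`. Rows with p outside (0, 1] or a
#' non-numeric position are dropped and counted.
#'
#' @param path path to the delimited file.
#' @param column_map named character vector resolving the logical columns
#'   `marker`, `chrom`, `pos`, `p` to header names.
#' @return A data.frame of class `association_table` with columns `marker`,
#'   `chrom`, `pos`, `p`, sorted by (chrom, pos); attribute `n_dropped`
#'   counts discarded rows.
#' @export
read_association <- function(path,
                             column_map = c(marker = "Marker", chrom = "Locus",
                                            pos = "Site", p = "p")) {
  if (!file.exists(path)) io_error(sprintf("cannot read association file: %s", path))
  needed <- c("marker", "chrom", "pos", "p")
  if (!all(needed %in% names(column_map)))
    usage_error(sprintf("column_map must name: %s", paste(needed, collapse = ", ")))
  header_line <- readLines(path, n = 1L)
  seps <- c("\t" = lengths(regmatches(header_line, gregexpr("\t", header_line))),
            "," = lengths(regmatches(header_line, gregexpr(",", header_line))),
            ";" = lengths(regmatches(header_line, gregexpr(";", header_line))))
  sep <- names(seps)[which.max(seps)]
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(unname(column_map[needed]), names(df))
  if (length(miss) > 0)
    usage_error(sprintf("association table lacks column(s) %s; available: %s",
                        paste(miss, collapse = ", "),
                        paste(names(df), collapse = ", ")))
  out <- data.frame(marker = as.character(df[[column_map["marker"]]]),
                    chrom  = as.character(df[[column_map["chrom"]]]),
                    pos    = suppressWarnings(as.integer(df[[column_map["pos"]]])),
                    p      = suppressWarnings(as.numeric(df[[column_map["p"]]])))
  bad <- is.na(out$pos) | is.na(out$p) | out$p <= 0 | out$p > 1
  out <- out[!bad, , drop = FALSE]
  out <- out[order_chrom_pos(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Write an association table as TSV
#'
#' @param assoc an `association_table` (or data.frame with columns `marker`,
#'   `chrom`, `pos`, `p`).
#' @param path output path.
#' @param headers header names to use for the four columns, defaulting to the
#'   TASSEL-style names [read_association] expects.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path,
                              headers = c("Marker", "Locus", "Site", "p")) {
  df <- data.frame(assoc$marker, assoc$chrom, assoc$pos,
                   formatC(assoc$p, format = "g", digits = 8))
  names(df) <- headers
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write association file: %s", path))
  invisible(path)
}
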