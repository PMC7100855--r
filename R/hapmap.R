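HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Construct a genotype matrix
#'
#' Container for biallelic SNP calls encoded as minor-allele dosage.
#'
#' @param markers data.frame with columns `name`, `chrom`, `pos`, `minor`,
#'   `major` (one row per marker, sorted by chromosome then position).
#' @param samples character vector of sample identifiers.
#' @param dosage integer matrix, markers x samples, values in `{0, 1, 2, NA}`
#'   counting copies of the minor allele.
#' @param report load report: counts of retained/dropped markers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, samples, dosage,
                            report = list(n_input = nrow(markers),
                                          n_retained = nrow(markers),
                                          n_dropped = 0L,
                                          dropped = data.frame(name = character(),
                                                               reason = character()))) {
  stopifnot(is.data.frame(markers),
            all(c("name", "chrom", "pos", "minor", "major") %in% names(markers)),
            nrow(dosage) == nrow(markers),
            ncol(dosage) == length(samples))
  ok <- is.na(dosage) | (dosage %in% 0:2)
  if (!all(ok)) stop("dosage values must be in {0, 1, 2, NA}")
  rownames(dosage) <- markers$name
  colnames(dosage) <- samples
  structure(list(markers = markers, samples = samples,
                 dosage = dosage, report = report),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples\n",
              nrow(x$markers), length(x$samples)))
  if (nrow(x$markers) > 0) {
    cat(sprintf("  chrom %s, pos %s..%s\n",
                paste(unique(x$markers$chrom), collapse = ","),
                format(min(x$markers$pos), big.mark = ","),
                format(max(x$markers$pos), big.mark = ",")))
  }
  cat(sprintf("  load report: %d input, %d retained, %d dropped\n",
              x$report$n_input, x$report$n_retained, x$report$n_dropped))
  invisible(x)
}

# numeric-aware chromosome ordering ("2" before "10", non-numeric names last)
order_chrom_pos <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, pos)
}

# Decode a character matrix of diploid calls into two allele-character
# matrices (a1, a2); unresolved/missing calls become NA in both.
decode_calls <- function(calls, dialect) {
  if (dialect == "two-letter") {
    a1 <- substr(calls, 1L, 1L)
    a2 <- substr(calls, 2L, 2L)
    a2[nchar(calls) == 1L] <- a1[nchar(calls) == 1L]  # tolerate single letters
  } else {                                            # iupac
    a1 <- calls
    a2 <- calls
    het <- calls %in% names(IUPAC_HET)
    a1[het] <- substr(IUPAC_HET[calls[het]], 1L, 1L)
    a2[het] <- substr(IUPAC_HET[calls[het]], 2L, 2L)
  }
  miss <- a1 %in% c("N", "-", "") | a2 %in% c("N", "-", "")
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  dim(a1) <- dim(calls); dim(a2) <- dim(calls)
  list(a1 = a1, a2 = a2)
}

#' Read genotypes from a HapMap text file
#'
#' Parses the tab-separated HapMap genotype format (11 fixed metadata columns
#' followed by one column per sample). Diploid calls may be two-letter
#' (`"AG"`) or single-letter IUPAC codes (`"R"` for an A/G heterozygote);
#' `dialect = "auto"` detects the convention from call width. `"NN"`, `"N"`
#' and `"--"` are missing. Markers with more than two observed alleles, or
#' with no non-missing call, are dropped and counted in the load report. The
#' minor allele is determined empirically from observed allele frequencies
#' (ties broken alphabetically); the file's `alleles` column is advisory only.
#'
#' @param path path to a HapMap genotype file.
#' @param dialect one of `"auto"`, `"two-letter"`, `"iupac"`.
#' @return A [genotype_matrix] sorted by (chrom, pos), with a load report in
#'   `$report`.
#' @export
read_hapmap <- function(path, dialect = c("auto", "two-letter", "iupac")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error(sprintf("cannot read HapMap file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) format_error("HapMap file is empty (no header)")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 12L)
    format_error("HapMap header has fewer than 12 tab-separated columns")
  missing_cols <- HAPMAP_COLS[tolower(HAPMAP_COLS) != tolower(header[1:11])]
  if (length(missing_cols) > 0)
    format_error(sprintf("HapMap header missing fixed column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  samples <- header[-(1:11)]

  body <- lines[-1L]
  body <- body[nzchar(body)]
  n_in <- length(body)
  if (n_in == 0) {
    return(genotype_matrix(
      data.frame(name = character(), chrom = character(), pos = integer(),
                 minor = character(), major = character()),
      samples, matrix(NA_integer_, 0, length(samples)),
      report = list(n_input = 0L, n_retained = 0L, n_dropped = 0L,
                    dropped = data.frame(name = character(), reason = character()))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad) > 0)
    format_error(sprintf("line %d: expected %d columns, found %d",
                         bad[1L] + 1L, length(header), nf[bad[1L]]))
  m <- matrix(unlist(fields), nrow = n_in, byrow = TRUE)
  name  <- m[, 1L]
  chrom <- m[, 3L]
  pos   <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    format_error(sprintf("line %d: non-integer position '%s' for marker '%s'",
                         i + 1L, m[i, 4L], name[i]))
  }
  calls <- m[, -(1:11), drop = FALSE]

  if (dialect == "auto") {
    w <- nchar(calls)
    nonmiss <- !(calls %in% c("N", "NN", "--", "-", ""))
    dialect <- if (any(w[nonmiss] == 2L)) "two-letter" else "iupac"
  }
  al <- decode_calls(calls, dialect)

  minor <- character(n_in); major <- character(n_in)
  keep <- logical(n_in); reason <- rep(NA_character_, n_in)
  dosage <- matrix(NA_integer_, n_in, length(samples))
  for (i in seq_len(n_in)) {
    a <- c(al$a1[i, ], al$a2[i, ])
    tab <- table(a[!is.na(a)])
    if (length(tab) == 0L) { reason[i] <- "no informative calls"; next }
    if (length(tab) > 2L)  { reason[i] <- "more than 2 alleles";  next }
    keep[i] <- TRUE
    alleles <- names(tab)[order(tab, names(tab))]  # ascending count, ties alphabetical
    if (length(alleles) == 1L) {
      minor[i] <- NA_character_; major[i] <- alleles[1L]
      dosage[i, !is.na(al$a1[i, ])] <- 0L
    } else {
      minor[i] <- alleles[1L]; major[i] <- alleles[2L]
      dosage[i, ] <- (al$a1[i, ] == minor[i]) + (al$a2[i, ] == minor[i])
    }
  }

  ord <- order_chrom_pos(chrom[keep], pos[keep])
  markers <- data.frame(name = name[keep], chrom = chrom[keep], pos = pos[keep],
                        minor = minor[keep], major = major[keep])[ord, , drop = FALSE]
  rownames(markers) <- NULL
  dropped <- data.frame(name = name[!keep], reason = reason[!keep])
  genotype_matrix(markers, samples,
                  dosage[keep, , drop = FALSE][ord, , drop = FALSE],
                  report = list(n_input = n_in, n_retained = sum(keep),
                                n_dropped = sum(!keep), dropped = dropped))
}

#' Write a genotype matrix to a HapMap text file
#'
#' Two-letter diploid calls; heterozygotes written with alleles in
#' alphabetical order; missing calls as `"NN"`.
#'
#' @param gt a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_matrix"))
  mk <- gt$markers
  n <- nrow(mk)
  allele_col <- ifelse(is.na(mk$minor), paste0(mk$major, "/", mk$major),
                       paste0(mk$minor, "/", mk$major))
  call_of <- function(i) {
    a <- sort(c(mk$minor[i], mk$major[i]))
    hom_major <- strrep(mk$major[i], 2L)
    hom_minor <- if (is.na(mk$minor[i])) hom_major else strrep(mk$minor[i], 2L)
    het <- if (is.na(mk$minor[i])) hom_major else paste0(a[1L], a[2L])
    out <- c(hom_major, het, hom_minor)[gt$dosage[i, ] + 1L]
    out[is.na(out)] <- "NN"
    out
  }
  rows <- vapply(seq_len(n), function(i) {
    paste(c(mk$name[i], allele_col[i], mk$chrom[i], mk$pos[i], "+",
            "NA", "NA", "NA", "NA", "NA", "NA", call_of(i)), collapse = "\t")
  }, character(1L))
  out <- c(paste(c(HAPMAP_COLS, gt$samples), collapse = "\t"), rows)
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write HapMap file: %s", path))
  invisible(path)
}

#' Subset a genotype matrix by marker
#'
#' @param gt a [genotype_matrix].
#' @param idx marker indices (or logical vector), in the order to keep.
#' @return A [genotype_matrix] with the selected markers.
#' @export
gt_subset <- function(gt, idx) {
  mk <- gt$markers[idx, , drop = FALSE]
  rownames(mk) <- NULL
  genotype_matrix(mk, gt$samples, gt$dosage[idx, , drop = FALSE],
                  report = gt$report)
}
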