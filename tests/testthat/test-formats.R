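test_that("read_hapmap decodes two-letter calls into minor-allele dosage", {
  f <- write_toy_hapmap(c(
    hapmap_row("mk1", "9", 100, c("AA", "AG", "GG", "GG")),
    hapmap_row("mk2", "9", 300, c("GG", "GG", "GG", "AG")),
    hapmap_row("mk3", "9", 200, c("AA", "AA", "AA", "AG"))))
  gt <- read_hapmap(f)
  # sorted by position
  expect_equal(gt$markers$name, c("mk1", "mk3", "mk2"))
  # mk1: 4 A vs 4 G -> tie broken alphabetically, minor = A
  expect_equal(gt$markers$minor[1], "A")
  expect_equal(unname(gt$dosage["mk1", ]), c(2L, 1L, 0L, 0L))
  # mk2: A is rare -> minor
  expect_equal(gt$markers$minor[3], "A")
  expect_equal(unname(gt$dosage["mk2", ]), c(0L, 0L, 0L, 1L))
  # mk3: G is rare -> minor
  expect_equal(gt$markers$minor[2], "G")
  expect_equal(unname(gt$dosage["mk3", ]), c(0L, 0L, 0L, 1L))
  expect_equal(gt$report$n_input,
               gt$report$n_retained + gt$report$n_dropped)
})

test_that("read_hapmap drops uninformative and non-biallelic markers", {
  f <- write_toy_hapmap(c(
    hapmap_row("ok1", "9", 100, c("AA", "AG", "GG", "GG")),
    hapmap_row("allmiss", "9", 200, c("NN", "NN", "NN", "NN")),
    hapmap_row("tri", "9", 300, c("AA", "AC", "AG", "AA"))))
  gt <- read_hapmap(f)
  expect_equal(gt$report$n_dropped, 2L)
  expect_setequal(gt$report$dropped$name, c("allmiss", "tri"))
  expect_equal(gt$markers$name, "ok1")
  expect_equal(gt$report$n_input, 3L)
})

test_that("read_hapmap understands IUPAC single-letter calls and auto-detects", {
  f <- write_toy_hapmap(c(
    hapmap_row("mk1", "2", 50, c("A", "R", "G", "G"))))
  for (dia in c("iupac", "auto")) {
    gt <- read_hapmap(f, dialect = dia)
    expect_equal(unname(gt$dosage["mk1", ]), c(2L, 1L, 0L, 0L))
  }
})

test_that("read_hapmap reports malformed headers and bad positions", {
  f <- tempfile()
  writeLines(c(paste(c("rs#", "alleles", "chrom", "WRONG", "strand",
                       "assembly#", "center", "protLSID", "assayLSID",
                       "panelLSID", "QCcode", "s1"), collapse = "\t"),
               "a\tA/G\t1\t10\t+\tNA\tNA\tNA\tNA\tNA\tNA\tAA"), f)
  expect_error(read_hapmap(f), "pos", class = "ldassoc_format_error")
  f2 <- write_toy_hapmap(hapmap_row("mk1", "9", "12x", c("AA", "AA", "AA", "AA")))
  expect_error(read_hapmap(f2), "line 2", class = "ldassoc_format_error")
})

test_that("HapMap write/read round trip preserves the panel exactly", {
  gt <- fx_panel()
  # inject missingness to exercise the NN path
  gt$dosage[cbind(c(1, 5, 9), c(2, 3, 4))] <- NA_integer_
  f <- tempfile(fileext = ".hmp.txt")
  write_hapmap(gt, f)
  gt2 <- read_hapmap(f)
  expect_equal(gt2$markers, gt$markers)
  expect_equal(gt2$samples, gt$samples)
  expect_equal(unname(gt2$dosage), unname(gt$dosage))
  expect_equal(gt2$report$n_dropped, 0L)
  expect_false(is.unsorted(gt2$markers$pos))
})

test_that("read_gtf builds transcript models and gene spans", {
  f <- tempfile(fileext = ".gtf")
  attr_ <- 'gene_id "g1"; transcript_id "g1_T01";'
  writeLines(c(
    sprintf("9\tsrc\texon\t%d\t%d\t.\t+\t.\t%s", c(100, 300, 600),
            c(200, 400, 700), attr_),
    sprintf("9\tsrc\tCDS\t%d\t%d\t.\t+\t.\t%s", c(150, 300), c(200, 380), attr_),
    sprintf("9\tsrc\tstart_codon\t150\t152\t.\t+\t.\t%s", attr_)), f)
  ann <- read_gtf(f)
  tx <- ann$transcripts[["g1_T01"]]
  expect_equal(nrow(tx$features), 5L)    # unknown kinds ignored
  expect_equal(c(tx$start, tx$end), c(100, 700))
  expect_equal(ann$genes$start, 100)
  expect_equal(ann$genes$end, 700)
})

test_that("read_gtf handles empty files and multi-transcript genes", {
  f <- tempfile(fileext = ".gtf")
  writeLines(character(), f)
  ann <- read_gtf(f)
  expect_s3_class(ann, "annotation_set")
  expect_equal(length(ann$transcripts), 0L)

  f2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    '9\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    '9\tsrc\texon\t100\t500\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'), f2)
  ann2 <- read_gtf(f2)
  expect_setequal(ann2$genes$transcript_ids[[1]], c("t1", "t2"))
  expect_equal(ann2$genes$end, 500)   # union of transcript spans
})

test_that("read_gtf skips exon rows without transcript_id, with a warning", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    '9\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    '9\tsrc\texon\t900\t950\t.\t+\t.\tgene_id "g1";'), f)
  expect_warning(ann <- read_gtf(f), "transcript_id")
  expect_equal(ann$transcripts[["t1"]]$end, 200)
})

test_that("toy annotation round-trips through the GTF writer and reader", {
  ann <- fx_ann()
  f <- tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  ann2 <- read_gtf(f)
  expect_setequal(names(ann2$transcripts), names(ann$transcripts))
  for (id in names(ann$transcripts)) {
    a <- ann$transcripts[[id]]; b <- ann2$transcripts[[id]]
    expect_equal(b$strand, a$strand)
    fa <- a$features[order(a$features$start, a$features$kind), ]
    fb <- b$features[order(b$features$start, b$features$kind), ]
    expect_equal(fb$kind, fa$kind)
    expect_equal(fb$start, fa$start)
    expect_equal(fb$end, fa$end)
  }
})

test_that("read_association filters, sorts, and remaps columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("Marker\tLocus\tSite\tp",
               "mk3\t9\t94178074\t1e-7",
               "mk1\t9\t100\t0",          # p = 0: -log10 undefined
               "mk2\t9\t50\t0.02"), f)
  a <- read_association(f)
  expect_equal(a$marker, c("mk2", "mk3"))   # sorted by position
  expect_equal(attr(a, "n_dropped"), 1L)
  expect_equal(-log10(a$p[2]), 7)

  # comma-separated with custom headers
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("snp,chr,bp,pval", "x,1,10,0.5"), f2)
  a2 <- read_association(f2, column_map = c(marker = "snp", chrom = "chr",
                                            pos = "bp", p = "pval"))
  expect_equal(a2$marker, "x")

  expect_error(read_association(f2), "available",
               class = "ldassoc_usage_error")
})

test_that("write_ld_table emits the documented columns at 6 decimals", {
  # two markers engineered to haplotype counts AB=40, Ab=10, aB=10, ab=40
  di <- rep(c(2, 2, 0, 0), c(20, 5, 5, 20))
  dj <- rep(c(2, 0, 2, 0), c(20, 5, 5, 20))
  mk <- data.frame(name = c("a", "b"), chrom = "9", pos = c(1L, 2L),
                   minor = "A", major = "G")
  gt <- genotype_matrix(mk, paste0("s", 1:50), rbind(di, dj))
  lm_ <- ld_matrix(gt)
  f <- tempfile(fileext = ".tsv")
  write_ld_table(lm_, f)
  out <- read.delim(f, colClasses = "character")
  expect_equal(names(out), c("markerA", "markerB", "chromA", "posA",
                             "chromB", "posB", "r2", "Dprime", "n"))
  expect_equal(out$r2, "0.360000")
  expect_equal(out$Dprime, "0.600000")

  # empty matrix -> header only
  gt1 <- genotype_matrix(mk[1, , drop = FALSE], paste0("s", 1:50),
                         matrix(di, nrow = 1))
  suppressWarnings(empty <- ld_matrix(gt1))
  f2 <- tempfile(fileext = ".tsv")
  write_ld_table(empty, f2)
  expect_equal(length(readLines(f2)), 1L)
})
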