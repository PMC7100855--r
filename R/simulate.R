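# Seeded generators for the three input types. The genotype model is a
# haplotype-block mixture: within a block each haplotype either copies a
# shared latent ancestral draw (probability = the target |D'|) or draws its
# alleles independently at the block's allele frequencies. Because both
# components preserve the per-locus allele frequencies, the population
# haplotype frequency for any within-block pair is
#   pAB = t * min(pA, pB) + (1 - t) * pA * pB,
# i.e. D = t * Dmax, so the population |D'| equals the target t exactly;
# between blocks loci are independent. This gives exact control of LD
# without an external coalescent simulator.

#' Specify a haplotype-block genotype simulation
#'
#' @param n_blocks number of independent LD blocks.
#' @param markers_per_block markers in each block.
#' @param within_block_Dprime target population |D'| for within-block pairs,
#'   in \[0, 1\].
#' @param maf_range (min, max) of per-marker minor-allele frequencies, in
#'   (0, 0.5].
#' @param n_samples number of diploid samples.
#' @param seed mandatory integer seed; generation is fully reproducible.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(n_blocks = 10, markers_per_block = 10,
                       within_block_Dprime = 0.8, maf_range = c(0.1, 0.5),
                       n_samples = 100, seed) {
  if (missing(seed)) usage_error("block_spec requires an explicit seed")
  if (n_blocks < 1 || markers_per_block < 1 || n_samples < 1)
    usage_error("block_spec counts must be >= 1")
  if (within_block_Dprime < 0 || within_block_Dprime > 1)
    usage_error("within_block_Dprime must be in [0, 1]")
  if (maf_range[1] <= 0 || maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    usage_error("maf_range must satisfy 0 < min <= max <= 0.5")
  structure(list(n_blocks = n_blocks, markers_per_block = markers_per_block,
                 within_block_Dprime = within_block_Dprime,
                 maf_range = maf_range, n_samples = n_samples,
                 seed = as.integer(seed)),
            class = "block_spec")
}

#' Simulate a genotype panel with block LD structure
#'
#' Simulates `2 * n_samples` haplotypes under the block mixture model (see
#' [block_spec]), pairs them randomly into unphased diploid calls, and places
#' markers uniformly in the region. The returned dosages count the
#' empirically minor allele (ties broken alphabetically), matching what
#' [read_hapmap] reconstructs, so a write/read round trip is exact.
#'
#' @param spec a [block_spec].
#' @param region a [region_spec] giving chromosome and window.
#' @return A [genotype_matrix]; marker names are `mk<block>_<index>`.
#' @export
simulate_genotypes <- function(spec, region) {
  stopifnot(inherits(spec, "block_spec"), inherits(region, "region_spec"))
  set.seed(spec$seed)
  n_mk <- spec$n_blocks * spec$markers_per_block
  n_hap <- 2L * spec$n_samples
  t <- spec$within_block_Dprime

  if (region$right - region$left + 1 < n_mk)
    usage_error("region too narrow for the requested marker count")
  pos <- sort(sample(seq(region$left, region$right), n_mk, replace = FALSE))
  maf <- stats::runif(n_mk, spec$maf_range[1], spec$maf_range[2])
  block <- rep(seq_len(spec$n_blocks), each = spec$markers_per_block)

  # haplotypes: minor-allele indicators, markers x haplotypes
  hap <- matrix(0L, n_mk, n_hap)
  for (b in seq_len(spec$n_blocks)) {
    rows <- which(block == b)
    u_shared <- stats::runif(n_hap)             # latent ancestral draw
    copies <- stats::runif(n_hap) < t           # haplotype-level mixture
    for (r in rows) {
      u <- ifelse(copies, u_shared, stats::runif(n_hap))
      hap[r, ] <- as.integer(u < maf[r])
    }
  }
  # random pairing into diploids
  perm <- sample.int(n_hap)
  dosage <- hap[, perm[seq_len(spec$n_samples)], drop = FALSE] +
            hap[, perm[spec$n_samples + seq_len(spec$n_samples)], drop = FALSE]

  # allele letters per marker; dosage recoded to the empirically minor allele
  letters2 <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                     ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, n_mk, replace = TRUE)
  sim_minor <- letters2[pick, 1L]
  sim_major <- letters2[pick, 2L]
  freq <- rowMeans(dosage) / 2
  flip <- freq > 0.5 | (freq == 0.5 & sim_major < sim_minor)
  dosage[flip, ] <- 2L - dosage[flip, ]
  minor <- ifelse(flip, sim_major, sim_minor)
  major <- ifelse(flip, sim_minor, sim_major)
  mono <- rowSums(dosage) == 0
  minor[mono] <- NA_character_

  markers <- data.frame(
    name = sprintf("mk%02d_%03d", block, seq_len(n_mk)),
    chrom = region$chrom, pos = pos, minor = minor, major = major)
  genotype_matrix(markers, sprintf("s%04d", seq_len(spec$n_samples)),
                  dosage)
}

#' Simulate a GWAS association table from a genotype panel
#'
#' Phenotype = `effect * dosage(causal) + N(0, 1)` noise; each marker is
#' tested by simple linear regression of phenotype on dosage (score test),
#' with missing dosages mean-imputed per marker.
#'
#' @param gt a [genotype_matrix].
#' @param causal causal marker (name, or anything with `chrom`/`pos`).
#' @param effect additive effect size per minor-allele copy.
#' @param seed integer seed for the phenotype noise.
#' @return An `association_table` (marker, chrom, pos, p) sorted by
#'   position.
#' @export
simulate_association <- function(gt, causal, effect = 1, seed) {
  stopifnot(inherits(gt, "genotype_matrix"))
  if (missing(seed)) usage_error("simulate_association requires a seed")
  set.seed(as.integer(seed))
  ci <- resolve_marker_ref(gt, causal)
  n <- length(gt$samples)
  dc <- gt$dosage[ci, ]
  dc[is.na(dc)] <- mean(dc, na.rm = TRUE)
  y <- effect * dc + stats::rnorm(n)

  D <- gt$dosage
  if (anyNA(D)) {
    mu <- rowMeans(D, na.rm = TRUE)
    D[is.na(D)] <- mu[row(D)[is.na(D)]]
  }
  sdx <- apply(D, 1L, stats::sd)
  r <- as.numeric(D %*% (y - mean(y))) / ((n - 1) * sdx * stats::sd(y))
  r[sdx == 0] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)

  out <- data.frame(marker = gt$markers$name, chrom = gt$markers$chrom,
                    pos = gt$markers$pos, p = p)
  out <- out[order_chrom_pos(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- 0L
  class(out) <- c("association_table", "data.frame")
  out
}

#' Generate a toy gene annotation
#'
#' Deterministically (from the seed) lays out `n_genes` non-overlapping
#' single-transcript gene models inside the region, each with 2-6 exons, a
#' CDS contained in the exons, UTR boxes at the transcript ends, and
#' alternating strands.
#'
#' @param region a [region_spec].
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return An [annotation_set]; gene ids are `GENE<k>`, transcripts
#'   `GENE<k>_T01`.
#' @export
toy_gtf <- function(region, n_genes = 5, seed) {
  stopifnot(inherits(region, "region_spec"))
  if (missing(seed)) usage_error("toy_gtf requires a seed")
  set.seed(as.integer(seed))
  span <- region$right - region$left
  if (span < n_genes * 60) usage_error("region too narrow for n_genes")
  slot <- span / n_genes
  txs <- vector("list", n_genes)
  for (k in seq_len(n_genes)) {
    slot_l <- round(region$left + (k - 1) * slot)
    glen <- round(stats::runif(1, 0.3, 0.8) * slot)
    gstart <- slot_l + round(stats::runif(1, 0.02, 0.15) * slot)
    gend <- min(gstart + max(glen, 50), region$right)
    n_ex <- sample(2:6, 1L)
    cuts <- sort(sample(seq(gstart + 10, gend - 10), 2L * (n_ex - 1L)))
    bounds <- c(gstart, cuts, gend)
    ex_start <- bounds[seq(1, length(bounds), by = 2)]
    ex_end <- bounds[seq(2, length(bounds), by = 2)]
    strand <- if (k %% 2 == 1) "+" else "-"
    # CDS = exons clipped to an interior coding span; UTRs outside it
    cds_l <- ex_start[1L] + max(1, round((ex_end[1L] - ex_start[1L]) * 0.3))
    cds_r <- ex_end[n_ex] - max(1, round((ex_end[n_ex] - ex_start[n_ex]) * 0.3))
    feats <- data.frame(kind = "exon", start = ex_start, end = ex_end)
    cs <- pmax(ex_start, cds_l); ce <- pmin(ex_end, cds_r)
    ok <- cs <= ce
    feats <- rbind(feats, data.frame(kind = "CDS", start = cs[ok], end = ce[ok]))
    utr5 <- data.frame(kind = if (strand == "+") "five_prime_UTR"
                              else "three_prime_UTR",
                       start = ex_start[1L], end = cds_l - 1L)
    utr3 <- data.frame(kind = if (strand == "+") "three_prime_UTR"
                              else "five_prime_UTR",
                       start = cds_r + 1L, end = ex_end[n_ex])
    if (utr5$start <= utr5$end) feats <- rbind(feats, utr5)
    if (utr3$start <= utr3$end) feats <- rbind(feats, utr3)
    feats <- feats[order(feats$start, feats$end), , drop = FALSE]
    rownames(feats) <- NULL
    txs[[k]] <- transcript_model(sprintf("GENE%d_T01", k), sprintf("GENE%d", k),
                                 region$chrom, strand, feats)
  }
  annotation_set(txs)
}
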