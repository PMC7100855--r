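# Fixtures are built in code, deterministically. The cache avoids repeating
# the medium-sized simulations across test files.

.fx <- new.env(parent = emptyenv())

fx_region <- function() region_spec("9", 94178074 - 200000, 94178074 + 200000)

# standard simulated locus: 100 markers in 10 LD blocks, 150 samples
fx_panel <- function() {
  if (is.null(.fx$panel)) {
    .fx$panel <- simulate_genotypes(
      block_spec(n_blocks = 10, markers_per_block = 10,
                 within_block_Dprime = 0.8, maf_range = c(0.15, 0.5),
                 n_samples = 150, seed = 42),
      fx_region())
  }
  .fx$panel
}

fx_assoc <- function() {
  if (is.null(.fx$assoc))
    .fx$assoc <- simulate_association(fx_panel(), causal = "mk05_050",
                                      effect = 1, seed = 43)
  .fx$assoc
}

fx_ann <- function() {
  if (is.null(.fx$ann)) .fx$ann <- toy_gtf(fx_region(), n_genes = 6, seed = 44)
  .fx$ann
}

fx_scope <- function(threshold = 5) {
  filter_significant(find_lead(resolve_region(fx_assoc(), fx_ann(),
                                              fx_region())),
                     threshold)
}

# on-disk fixture set for file-interface and CLI tests
fx_files <- function() {
  if (is.null(.fx$files)) {
    d <- file.path(tempdir(), "ldassoc-fx")
    dir.create(d, showWarnings = FALSE)
    p <- list(hapmap = file.path(d, "sim.hmp.txt"),
              gtf = file.path(d, "sim.gtf"),
              assoc = file.path(d, "sim_assoc.tsv"),
              dir = d)
    write_hapmap(fx_panel(), p$hapmap)
    write_gtf(fx_ann(), p$gtf)
    write_association(fx_assoc(), p$assoc)
    .fx$files <- p
  }
  .fx$files
}

# a second, partially overlapping genotype panel for cross-panel tests:
# same region, different block structure and seed
fx_panel2 <- function() {
  if (is.null(.fx$panel2)) {
    gt <- simulate_genotypes(
      block_spec(n_blocks = 12, markers_per_block = 10,
                 within_block_Dprime = 0.6, maf_range = c(0.15, 0.5),
                 n_samples = 80, seed = 77),
      fx_region())
    .fx$panel2 <- gt
  }
  .fx$panel2
}

# --- toy HapMap text ------------------------------------------------------

hapmap_header <- function(samples)
  paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
          "protLSID", "assayLSID", "panelLSID", "QCcode", samples),
        collapse = "\t")

hapmap_row <- function(name, chrom, pos, calls, alleles = "A/G")
  paste(c(name, alleles, chrom, pos, "+", rep("NA", 6), calls), collapse = "\t")

write_toy_hapmap <- function(rows, samples = paste0("s", seq_len(4))) {
  f <- tempfile(fileext = ".hmp.txt")
  writeLines(c(hapmap_header(samples), rows), f)
  f
}

# --- EM oracle ------------------------------------------------------------

# expand a flattened 3x3 count table (n00,n01,...,n22; second digit fastest)
# into dosage vectors
dosages_from_table <- function(N) {
  g <- expand.grid(g2 = 0:2, g1 = 0:2)[, 2:1]
  list(di = rep(g$g1, N), dj = rep(g$g2, N))
}

# profile log-likelihood in pAB with allele margins fixed at observed
# frequencies (EM preserves them); independent of the package EM path
profile_loglik <- function(pAB, pA, pB, N) {
  pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
  P <- c(pab^2, 2 * paB * pab, paB^2, 2 * pAb * pab,
         2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
         pAb^2, 2 * pAB * pAb, pAB^2)
  s <- N * log(P)
  s[N == 0] <- 0
  sum(s)
}

# brute-force maximizer: coarse grid + golden-section refinement; reports all
# grid modes within `tie_tol` of the maximum (non-unique maximizers happen
# for symmetric tables)
oracle_max <- function(N, pA, pB, tie_tol = 1e-6) {
  lo <- max(0, pA + pB - 1) + 1e-12
  hi <- min(pA, pB) - 1e-12
  grid <- seq(lo, hi, length.out = 2001)
  ll <- vapply(grid, profile_loglik, 0, pA = pA, pB = pB, N = N)
  best <- which.max(ll)
  refine <- function(i) {
    stats::optimize(profile_loglik,
                    c(grid[max(1, i - 2)], grid[min(length(grid), i + 2)]),
                    pA = pA, pB = pB, N = N, maximum = TRUE, tol = 1e-12)
  }
  top <- refine(best)
  # other local modes tied with the global max
  near <- which(ll > top$objective - tie_tol)
  if (length(near) == 0)
    return(list(pAB = top$maximum, loglik = top$objective,
                modes = top$maximum))
  gaps <- which(diff(near) > 1)
  starts <- c(near[1], near[gaps + 1])
  ends <- c(near[gaps], near[length(near)])
  modes <- unique(vapply(seq_along(starts), function(k) {
    i <- starts[k] + which.max(ll[starts[k]:ends[k]]) - 1L
    refine(i)$maximum
  }, 0))
  list(pAB = top$maximum, loglik = top$objective, modes = modes)
}

# all flattened 3x3 tables with total count 1..nmax (stars and bars)
enumerate_tables <- function(nmax) {
  out <- list()
  for (n in seq_len(nmax)) {
    cmp <- t(utils::combn(n + 8, 8))
    for (r in seq_len(nrow(cmp)))
      out[[length(out) + 1L]] <- diff(c(0, cmp[r, ], n + 9)) - 1
  }
  out
}

# independent LD oracle: expand haplotype frequencies into a pseudo-
# population and take plain correlations / a grid-based D'
brute_ld <- function(pAB, pAb, paB, pab, scale = 1e6) {
  counts <- round(c(pAB, pAb, paB, pab) * scale)
  x <- rep(c(1, 1, 0, 0), counts)
  y <- rep(c(1, 0, 1, 0), counts)
  r2 <- stats::cor(x, y)^2
  pA <- mean(x); pB <- mean(y)
  D <- mean(x * y) - pA * pB
  # max |D| attainable with these margins and the same sign of D
  cand <- seq(max(0, pA + pB - 1), min(pA, pB), length.out = 200001) - pA * pB
  cand <- cand[sign(cand) == sign(D) | cand == 0]
  list(D = D, r2 = r2, Dprime = if (D == 0) 0 else abs(D) / max(abs(cand)))
}
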