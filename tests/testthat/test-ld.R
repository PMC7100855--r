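# expected values below were computed with the independent oracles in
# helper-fixtures.R (profile-likelihood grid, pseudo-population correlation)

test_that("EM equals direct haplotype counting when all phases are known", {
  # 50 diploids, zero double heterozygotes, haplotypes AB=40 Ab=10 aB=10 ab=40
  di <- rep(c(2, 2, 0, 0), c(20, 5, 5, 20))
  dj <- rep(c(2, 0, 2, 0), c(20, 5, 5, 20))
  f <- em_haplotype_freqs(di, dj)
  expect_equal(f$status, "ok")
  expect_equal(f$pAB, 0.40, tolerance = 1e-9)
  expect_equal(f$pAb, 0.10, tolerance = 1e-9)
  expect_equal(f$paB, 0.10, tolerance = 1e-9)
  expect_equal(f$pab, 0.40, tolerance = 1e-9)
  expect_equal(f$n_used, 50)
})

test_that("duplicated markers admit only coupling haplotypes", {
  di <- c(rep(0, 25), rep(1, 20), rep(2, 5))
  f <- em_haplotype_freqs(di, di)
  maf <- mean(di) / 2
  expect_equal(f$pAb, 0, tolerance = 1e-8)
  expect_equal(f$paB, 0, tolerance = 1e-8)
  expect_equal(f$pAB, maf, tolerance = 1e-8)
  ld <- ld_pair(f)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(ld$Dprime, 1, tolerance = 1e-6)
})

test_that("independent loci at n = 5000 give pAB near pA * pB", {
  set.seed(2024)
  x <- rbinom(5000, 2, 0.5)
  y <- rbinom(5000, 2, 0.5)
  f <- em_haplotype_freqs(x, y)
  # 3 Monte-Carlo SE of a haplotype frequency at p = 0.25, 10000 haplotypes
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(f$pAB - 0.25), se3)
})

test_that("EM handles missingness, monomorphic loci, and empty overlap", {
  f <- em_haplotype_freqs(c(0, 1, NA, 2), c(0, NA, 1, 2))
  expect_equal(f$n_used, 2)
  f2 <- em_haplotype_freqs(c(0, 0, 0, 0), c(0, 1, 2, 1))
  expect_equal(f2$status, "monomorphic")
  expect_true(is.na(f2$pAB))
  f3 <- em_haplotype_freqs(c(NA, 0), c(0, NA))
  expect_equal(f3$status, "insufficient_data")
  expect_error(em_haplotype_freqs(0:1, 0:2), class = "ldassoc_usage_error")
})

test_that("closed-form LD matches the worked example and the brute oracle", {
  ld <- ld_pair(list(pAB = 0.4, pAb = 0.1, paB = 0.1, pab = 0.4, status = "ok"))
  expect_equal(ld$D, 0.15)
  expect_equal(ld$r2, 0.36)
  expect_equal(ld$Dprime, 0.60)
  br <- brute_ld(0.4, 0.1, 0.1, 0.4)
  expect_equal(ld$r2, br$r2, tolerance = 1e-6)
  expect_equal(ld$Dprime, br$Dprime, tolerance = 1e-4)
  expect_equal(ld$D, br$D, tolerance = 1e-9)

  # equilibrium and complete coupling
  eq <- ld_pair(list(pAB = 0.15, pAb = 0.35, paB = 0.15, pab = 0.35,
                     status = "ok"))
  expect_equal(c(eq$D, eq$r2, eq$Dprime), c(0, 0, 0))
  cc <- ld_pair(list(pAB = 0.3, pAb = 0, paB = 0, pab = 0.7, status = "ok"))
  expect_equal(cc$Dprime, 1)
  expect_equal(cc$r2, 1)
  # and a repulsion-phase case, against the oracle
  rp <- ld_pair(list(pAB = 0.05, pAb = 0.35, paB = 0.45, pab = 0.15,
                     status = "ok"))
  brp <- brute_ld(0.05, 0.35, 0.45, 0.15)
  expect_equal(rp$r2, brp$r2, tolerance = 1e-6)
  expect_equal(rp$Dprime, brp$Dprime, tolerance = 1e-4)
  expect_lt(rp$D, 0)
})

test_that("LD is invariant to locus order and allele relabeling", {
  set.seed(7)
  for (k in 1:20) {
    di <- sample(0:2, 60, replace = TRUE)
    dj <- sample(0:2, 60, replace = TRUE)
    base <- ld_pair(em_haplotype_freqs(di, dj))
    if (base$status != "ok") next
    swapped <- ld_pair(em_haplotype_freqs(dj, di))
    flipped <- ld_pair(em_haplotype_freqs(2 - di, dj))
    expect_equal(swapped$r2, base$r2, tolerance = 1e-6)
    expect_equal(swapped$Dprime, base$Dprime, tolerance = 1e-6)
    expect_equal(flipped$r2, base$r2, tolerance = 1e-6)
    expect_equal(flipped$Dprime, base$Dprime, tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing on random genotype pairs", {
  set.seed(11)
  for (k in 1:25) {
    di <- sample(c(0:2, NA), 40, replace = TRUE)
    dj <- sample(c(0:2, NA), 40, replace = TRUE)
    f <- em_haplotype_freqs(di, dj)
    if (f$status != "ok") next
    expect_true(all(diff(f$loglik_trace) > -1e-9))
  }
})

test_that("EM agrees with the brute-force maximizer on random small tables", {
  set.seed(3)
  for (k in 1:40) {
    N <- as.numeric(rmultinom(1, sample(3:20, 1), prob = runif(9)))
    d <- dosages_from_table(N)
    f <- em_haplotype_freqs(d$di, d$dj)
    if (f$status != "ok") next
    o <- oracle_max(N, f$pAB + f$pAb, f$pAB + f$paB)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-6)
    expect_lt(min(abs(f$pAB - o$modes)), 1e-4)
  }
})

test_that("ld_matrix stores exactly n(n-1)/2 pairs and flags failures", {
  gt <- fx_panel()
  for (n in c(2, 5, 13)) {
    lm_ <- ld_matrix(gt, markers = gt$markers$name[seq_len(n)])
    expect_equal(nrow(lm_$pairs), n * (n - 1) / 2)
    expect_true(all(lm_$pairs$i < lm_$pairs$j))
  }
  # a monomorphic marker among 4 -> 3 of 6 pairs flagged
  mk <- data.frame(name = paste0("m", 1:4), chrom = "1", pos = 1:4 * 10L,
                   minor = "A", major = "G")
  dos <- rbind(sample(0:2, 30, TRUE), sample(0:2, 30, TRUE),
               rep(0L, 30), sample(0:2, 30, TRUE))
  g4 <- genotype_matrix(mk, paste0("s", 1:30), dos)
  lm4 <- ld_matrix(g4)
  expect_equal(nrow(lm4$pairs), 6L)
  expect_equal(sum(lm4$pairs$status == "monomorphic"), 3L)
  expect_warning(ld_matrix(g4, markers = "m1"), "fewer than 2")
})

test_that("ld_matrix agrees with per-pair EM", {
  gt <- fx_panel()
  lm_ <- ld_matrix(gt, markers = gt$markers$name[1:8])
  for (r in c(1, 10, 28)) {
    i <- lm_$pairs$i[r]; j <- lm_$pairs$j[r]
    f <- em_haplotype_freqs(gt$dosage[i, ], gt$dosage[j, ])
    p <- ld_pair(f)
    expect_equal(lm_$pairs$r2[r], p$r2, tolerance = 1e-8)
    expect_equal(lm_$pairs$Dprime[r], p$Dprime, tolerance = 1e-8)
  }
})

test_that("lead_snp_ld excludes self, finds duplicates, errors on absences", {
  gt5 <- gt_subset(fx_panel(), 1:5)
  v <- lead_snp_ld(gt5, gt5$markers$name[3])
  expect_equal(nrow(v), 4L)
  expect_false(gt5$markers$name[3] %in% v$name)
  expect_false(is.unsorted(v$pos))

  # duplicate the lead as another marker
  gt6 <- fx_panel()
  mk <- rbind(gt6$markers[1:5, ],
              within(gt6$markers[3, ], {name <- "dup"; pos <- pos + 1L}))
  dos <- gt6$dosage[c(1:5, 3), ]
  ord <- order(mk$pos)
  g <- genotype_matrix(mk[ord, ], gt6$samples, dos[ord, ])
  v2 <- lead_snp_ld(g, g$markers$name[g$markers$name == "dup"][1])
  orig <- v2[v2$pos == mk$pos[3], ]
  expect_equal(orig$r2, 1, tolerance = 1e-6)
  expect_equal(orig$Dprime, 1, tolerance = 1e-6)

  expect_error(lead_snp_ld(gt5, list(chrom = "9", pos = 1L)),
               "9:1", class = "ldassoc_lookup_error")
})

test_that("lead-SNP LD recovers simulated block structure", {
  reg <- region_spec("1", 1e6, 2e6)
  gt <- simulate_genotypes(
    block_spec(n_blocks = 2, markers_per_block = 6, within_block_Dprime = 1,
               maf_range = c(0.2, 0.5), n_samples = 500, seed = 314),
    reg)
  v <- lead_snp_ld(gt, gt$markers$name[1])
  same_block <- v$name %in% gt$markers$name[2:6]
  expect_true(all(v$Dprime[same_block & v$status == "ok"] > 1 - 1e-6))
  expect_lt(mean(v$r2[!same_block]), 0.05)
})

test_that("match_markers uses exact coordinates only", {
  gt <- fx_panel()
  a <- fx_assoc()
  m <- match_markers(a, gt)
  expect_equal(attr(m, "n_unmatched"), 0L)
  expect_equal(unname(m), seq_len(nrow(a)),   # identical panels -> identity
               ignore_attr = TRUE)

  shifted <- gt
  shifted$markers$pos <- shifted$markers$pos + 1L
  m2 <- match_markers(a, shifted)
  expect_equal(attr(m2, "n_unmatched"), nrow(a))

  sub <- gt_subset(gt, c(1:7, 30:60))
  m3 <- match_markers(a[1:10, ], sub)
  expect_equal(sum(!is.na(m3)), 7L)
  expect_equal(attr(m3, "n_unmatched"), 3L)
})
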