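# Two-locus LD from unphased diploid genotypes.
#
# For a pair of biallelic loci the data reduce to a 3x3 table of genotype
# counts n[g1, g2], g = minor-allele dosage. All cells except the double
# heterozygote (1,1) determine their haplotypes; EM resolves the coupling/
# repulsion phase of the double heterozygotes under HWE + random pairing.
# The engine is vectorized across tables so a full triangle matrix of pairs
# is one set of vector iterations, not millions of R-level EM calls.

# column order of a flattened 3x3 count table: n[g1][g2] with g2 fastest
COUNT_COLS <- c("n00", "n01", "n02", "n10", "n11", "n12", "n20", "n21", "n22")

EM_TOL <- 1e-8
EM_MAXIT <- 1000L

# multinomial log-likelihood of genotype tables given haplotype freqs
genotype_loglik <- function(N, pAB, pAb, paB, pab) {
  P <- cbind(pab^2, 2 * paB * pab, paB^2,
             2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
             pAb^2, 2 * pAB * pAb, pAB^2)
  # table order n00,n01,n02,n10,n11,n12,n20,n21,n22 matches P's columns
  contrib <- N * log(P)
  contrib[N == 0] <- 0
  rowSums(contrib)
}

# Vectorized EM over rows of a 9-column count matrix, from one start.
# `init`: "le" starts at linkage equilibrium; "coupling"/"repulsion" start
# near the feasible bounds of pAB (EM iterations preserve the observed allele
# margins, so the search is effectively one-dimensional in pAB). `trace`
# (single-table use) records the log-likelihood after every M-step.
em_engine_start <- function(N, init = "le", trace = FALSE) {
  np <- nrow(N)
  n_used <- rowSums(N)
  nA <- 2 * (N[, "n20"] + N[, "n21"] + N[, "n22"]) +
            (N[, "n10"] + N[, "n11"] + N[, "n12"])
  nB <- 2 * (N[, "n02"] + N[, "n12"] + N[, "n22"]) +
            (N[, "n01"] + N[, "n11"] + N[, "n21"])
  pA <- ifelse(n_used > 0, nA / (2 * n_used), NA_real_)
  pB <- ifelse(n_used > 0, nB / (2 * n_used), NA_real_)

  status <- rep("ok", np)
  status[n_used > 0 & (pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1)] <- "monomorphic"
  status[n_used == 0] <- "insufficient_data"

  pAB <- switch(init,
    le        = pA * pB,
    coupling  = 0.98 * pmin(pA, pB) + 0.02 * pA * pB,
    repulsion = 0.98 * pmax(0, pA + pB - 1) + 0.02 * pA * pB)
  pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
  pAB[status != "ok"] <- NA_real_; pAb[status != "ok"] <- NA_real_
  paB[status != "ok"] <- NA_real_; pab[status != "ok"] <- NA_real_

  # phase-known haplotype contributions; n11 is the latent cell
  cAB <- 2 * N[, "n22"] + N[, "n21"] + N[, "n12"]
  cAb <- 2 * N[, "n20"] + N[, "n21"] + N[, "n10"]
  caB <- 2 * N[, "n02"] + N[, "n12"] + N[, "n01"]
  cab <- 2 * N[, "n00"] + N[, "n01"] + N[, "n10"]
  nDH <- N[, "n11"]

  iterations <- integer(np)
  active <- which(status == "ok")
  ll_trace <- if (trace) genotype_loglik(N, pAB, pAb, paB, pab) else NULL
  it <- 0L
  while (length(active) > 0 && it < EM_MAXIT) {
    it <- it + 1L
    a <- active
    den <- pAB[a] * pab[a] + pAb[a] * paB[a]
    w <- ifelse(den > 0, pAB[a] * pab[a] / den, 0.5)
    tot <- 2 * n_used[a]
    nAB <- (cAB[a] + w * nDH[a]) / tot
    nab <- (cab[a] + w * nDH[a]) / tot
    nAb <- (cAb[a] + (1 - w) * nDH[a]) / tot
    naB <- (caB[a] + (1 - w) * nDH[a]) / tot
    delta <- pmax(abs(nAB - pAB[a]), abs(nAb - pAb[a]),
                  abs(naB - paB[a]), abs(nab - pab[a]))
    pAB[a] <- nAB; pAb[a] <- nAb; paB[a] <- naB; pab[a] <- nab
    if (trace)
      ll_trace <- c(ll_trace, genotype_loglik(N[a, , drop = FALSE],
                                              nAB, nAb, naB, nab))
    done <- delta < EM_TOL
    iterations[a[done]] <- it
    active <- a[!done]
  }
  iterations[active] <- EM_MAXIT  # cap hit

  loglik <- rep(NA_real_, np)
  ok <- status == "ok"
  if (any(ok))
    loglik[ok] <- genotype_loglik(N[ok, , drop = FALSE],
                                  pAB[ok], pAb[ok], paB[ok], pab[ok])
  out <- data.frame(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
                    n_used = n_used, loglik = loglik,
                    iterations = iterations, status = status)
  if (trace) attr(out, "loglik_trace") <- ll_trace
  out
}

# Multi-start EM: the linkage-equilibrium start can be a stationary saddle of
# the likelihood (e.g. a table of only double heterozygotes), so the engine
# also runs from near-coupling and near-repulsion starts and keeps, per
# table, the run with the highest final log-likelihood (earliest start wins
# ties, so results stay deterministic).
em_engine <- function(N, trace = FALSE) {
  N <- matrix(as.numeric(N), ncol = 9L, dimnames = list(NULL, COUNT_COLS))
  runs <- lapply(c("le", "coupling", "repulsion"),
                 function(s) em_engine_start(N, init = s, trace = trace))
  ll <- vapply(runs, function(r) r$loglik, numeric(nrow(N)))
  ll <- matrix(ll, nrow = nrow(N))
  ll[is.na(ll)] <- -Inf
  best <- max.col(ll, ties.method = "first")
  out <- runs[[1L]]
  for (s in 2:3) {
    take <- best == s
    if (any(take)) out[take, ] <- runs[[s]][take, , drop = FALSE]
  }
  if (trace) attr(out, "loglik_trace") <- attr(runs[[best[1L]]], "loglik_trace")
  out
}

# 3x3 count table (flattened, COUNT_COLS order) from two dosage vectors,
# pairwise-complete
pair_counts <- function(di, dj) {
  ok <- !is.na(di) & !is.na(dj)
  as.numeric(table(factor(di[ok], levels = 0:2), factor(dj[ok], levels = 0:2)))[
    c(1, 4, 7, 2, 5, 8, 3, 6, 9)]  # table() is column-major; reorder to n[g1][g2]
}

#' EM haplotype-frequency estimation for one marker pair
#'
#' Estimates the four two-locus haplotype frequencies from unphased diploid
#' dosages by expectation-maximization, using only samples non-missing at
#' both loci. Alleles are labelled A/a at locus 1 and B/b at locus 2, A and B
#' being the alleles counted by the dosage coding. Initialization is at
#' linkage equilibrium (product of observed allele frequencies); iteration
#' stops when the largest absolute frequency change is below 1e-8 or after
#' 1000 iterations (`iterations == 1000` flags a cap hit). The log-likelihood
#' is non-decreasing across iterations.
#'
#' @param dosages_i,dosages_j equal-length vectors of minor-allele dosages in
#'   `{0, 1, 2, NA}`.
#' @return An object of class `hap_freqs`: `pAB`, `pAb`, `paB`, `pab`,
#'   `n_used`, `loglik`, `iterations`, `status` (one of `"ok"`,
#'   `"monomorphic"`, `"insufficient_data"`), and `loglik_trace` (the
#'   log-likelihood after initialization and after each EM step).
#' @export
em_haplotype_freqs <- function(dosages_i, dosages_j) {
  if (length(dosages_i) != length(dosages_j))
    usage_error("dosage vectors must have equal length")
  bad <- c(dosages_i, dosages_j)
  if (!all(is.na(bad) | bad %in% 0:2))
    usage_error("dosages must be in {0, 1, 2, NA}")
  res <- em_engine(matrix(pair_counts(dosages_i, dosages_j), nrow = 1L),
                   trace = TRUE)
  structure(c(as.list(res[1L, ]),
              list(loglik_trace = attr(res, "loglik_trace"))),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf("hap_freqs [%s] n=%d iters=%d\n", x$status, x$n_used, x$iterations))
  if (x$status == "ok")
    cat(sprintf("  pAB=%.6f pAb=%.6f paB=%.6f pab=%.6f  loglik=%.4f\n",
                x$pAB, x$pAb, x$paB, x$pab, x$loglik))
  invisible(x)
}

# Closed-form LD measures from haplotype frequency vectors (vectorized).
# D = pAB - pA*pB; r2 = D^2 / (pA*pa*pB*pb); D' = D / Dmax with
# Dmax = min(pA*pb, pa*pB) if D > 0 else min(pA*pB, pa*pb); reported as |D'|.
ld_values <- function(pAB, pAb, paB, pab) {
  pA <- pAB + pAb; pB <- pAB + paB
  pa <- 1 - pA; pb <- 1 - pB
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * pa * pB * pb)
  dmax <- ifelse(D >= 0, pmin(pA * pb, pa * pB), pmin(pA * pB, pa * pb))
  dprime <- ifelse(D == 0, 0, abs(D / dmax))
  list(D = D, Dprime = pmin(dprime, 1), r2 = pmin(r2, 1))
}

#' LD measures from haplotype frequencies
#'
#' Computes the disequilibrium coefficient D, the normalized \eqn{|D'|}, and
#' \eqn{r^2} from four two-locus haplotype frequencies.
#'
#' @param freqs a `hap_freqs` object (from [em_haplotype_freqs]) or a list
#'   with elements `pAB`, `pAb`, `paB`, `pab`.
#' @param marker_i,marker_j optional marker metadata carried through to the
#'   result.
#' @return An object of class `ld_result` with `D` (signed), `Dprime`
#'   (\eqn{|D'|} in [0,1]), `r2` (in [0,1]), `freqs`, `status`. When either
#'   locus is monomorphic the status reflects it and the measures are `NA`.
#' @export
ld_pair <- function(freqs, marker_i = NULL, marker_j = NULL) {
  status <- if (!is.null(freqs$status)) freqs$status else "ok"
  if (status == "ok") {
    pA <- freqs$pAB + freqs$pAb; pB <- freqs$pAB + freqs$paB
    if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) status <- "monomorphic"
  }
  if (status != "ok") {
    v <- list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_)
  } else {
    v <- ld_values(freqs$pAB, freqs$pAb, freqs$paB, freqs$pab)
  }
  structure(list(marker_i = marker_i, marker_j = marker_j,
                 D = v$D, Dprime = v$Dprime, r2 = v$r2,
                 freqs = freqs, status = status),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("ld_result [%s] D=%s |D'|=%s r2=%s\n", x$status,
              format(x$D, digits = 4), format(x$Dprime, digits = 4),
              format(x$r2, digits = 4)))
  invisible(x)
}

# resolve a marker subset argument (NULL / names / indices / logical)
resolve_marker_subset <- function(gt, markers) {
  if (is.null(markers)) return(seq_len(nrow(gt$markers)))
  if (is.character(markers)) {
    idx <- match(markers, gt$markers$name)
    if (anyNA(idx))
      lookup_error(sprintf("markers not in genotype panel: %s",
                           paste(markers[is.na(idx)], collapse = ", ")))
  } else idx <- which(seq_len(nrow(gt$markers)) %in% seq_len(nrow(gt$markers))[markers])
  sort(idx)  # position order (markers are sorted by chrom, pos)
}

# dosage-level indicator matrices (samples x markers), NA -> 0
dosage_indicators <- function(dosage) {
  lapply(0:2, function(k) {
    x <- t(dosage == k)
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
}

#' Pairwise LD matrix over a marker panel
#'
#' Computes EM-based LD for every pair of markers in the (sub)panel, stored
#' as the strict lower triangle: exactly \eqn{n(n-1)/2} pairs for n markers.
#' Per-pair failures (monomorphic locus, no overlapping samples) are recorded
#' in the pair's `status`, never raised.
#'
#' @param gt a [genotype_matrix].
#' @param markers optional subset (marker names or indices); default all.
#' @param measure which measure the matrix nominally displays, `"r2"` or
#'   `"Dprime"` (both are stored).
#' @return An object of class `ld_matrix`: `$markers` (metadata, position
#'   order), `$pairs` (data.frame with `i`, `j` (i < j), `D`, `Dprime`, `r2`,
#'   `n_used`, `status`), `$measure`.
#' @export
ld_matrix <- function(gt, markers = NULL, measure = c("r2", "Dprime")) {
  measure <- match.arg(measure)
  stopifnot(inherits(gt, "genotype_matrix"))
  idx <- resolve_marker_subset(gt, markers)
  mk <- gt$markers[idx, , drop = FALSE]
  rownames(mk) <- NULL
  n <- nrow(mk)
  if (n < 2L) {
    warning("fewer than 2 markers: empty LD matrix")
    pairs <- data.frame(i = integer(), j = integer(), D = numeric(),
                        Dprime = numeric(), r2 = numeric(),
                        n_used = numeric(), status = character())
    return(structure(list(markers = mk, pairs = pairs, measure = measure),
                     class = "ld_matrix"))
  }
  X <- dosage_indicators(gt$dosage[idx, , drop = FALSE])
  jj <- rep.int(2:n, 1:(n - 1))     # upper-triangle, column-major: j
  ii <- sequence(1:(n - 1))         # paired i < j
  lin <- ii + (jj - 1L) * n
  N <- matrix(0, length(lin), 9L)
  col <- 0L
  for (g1 in 0:2) for (g2 in 0:2) {   # COUNT_COLS order: g2 fastest
    col <- col + 1L
    N[, col] <- crossprod(X[[g1 + 1L]], X[[g2 + 1L]])[lin]
  }
  res <- em_engine(N)
  v <- ld_values(res$pAB, res$pAb, res$paB, res$pab)
  pairs <- data.frame(i = ii, j = jj, D = v$D, Dprime = v$Dprime, r2 = v$r2,
                      n_used = res$n_used, status = res$status)
  structure(list(markers = mk, pairs = pairs, measure = measure),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d markers, %d pairs (%s)\n",
              nrow(x$markers), nrow(x$pairs), x$measure))
  if (nrow(x$pairs) > 0) {
    tab <- table(x$pairs$status)
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# find a marker in a panel by name or (chrom, pos); lead may be a name, a
# list/data.frame row with chrom+pos, or a 1-row markers slice
resolve_marker_ref <- function(gt, ref) {
  if (is.character(ref) && length(ref) == 1L) {
    idx <- match(ref, gt$markers$name)
    if (is.na(idx)) lookup_error(sprintf("marker '%s' not in genotype panel", ref))
    return(idx)
  }
  if (!is.null(ref$chrom) && !is.null(ref$pos)) {
    idx <- which(gt$markers$chrom == as.character(ref$chrom)[1L] &
                 gt$markers$pos == as.integer(ref$pos)[1L])
    if (length(idx) == 0)
      lookup_error(sprintf("no marker at %s:%d in genotype panel",
                           as.character(ref$chrom)[1L], as.integer(ref$pos)[1L]))
    return(idx[1L])
  }
  usage_error("marker reference must be a name or have chrom and pos")
}

#' LD of a lead SNP with every other marker
#'
#' Computes EM-based LD between one lead marker and each other marker in the
#' (sub)panel, in position order. The lead-vs-self entry is omitted.
#'
#' @param gt a [genotype_matrix].
#' @param lead the lead marker: a marker name, or anything with `chrom` and
#'   `pos` fields (exact match).
#' @param markers optional subset of panel markers (default all).
#' @return A data.frame of class `lead_ld`: marker metadata columns plus `D`,
#'   `Dprime`, `r2`, `n_used`, `status`; attribute `lead` holds the lead
#'   marker's metadata row.
#' @export
lead_snp_ld <- function(gt, lead, markers = NULL) {
  stopifnot(inherits(gt, "genotype_matrix"))
  lead_idx <- resolve_marker_ref(gt, lead)
  idx <- setdiff(resolve_marker_subset(gt, markers), lead_idx)
  dlead <- gt$dosage[lead_idx, ]
  xlead <- lapply(0:2, function(k) as.numeric(!is.na(dlead) & dlead == k))
  X <- dosage_indicators(gt$dosage[idx, , drop = FALSE])
  N <- matrix(0, length(idx), 9L)
  col <- 0L
  for (g1 in 0:2) for (g2 in 0:2) {
    col <- col + 1L
    N[, col] <- as.numeric(crossprod(xlead[[g1 + 1L]], X[[g2 + 1L]]))
  }
  res <- em_engine(N)
  v <- ld_values(res$pAB, res$pAb, res$paB, res$pab)
  out <- cbind(gt$markers[idx, c("name", "chrom", "pos")],
               data.frame(D = v$D, Dprime = v$Dprime, r2 = v$r2,
                          n_used = res$n_used, status = res$status))
  rownames(out) <- NULL
  attr(out, "lead") <- gt$markers[lead_idx, , drop = FALSE]
  class(out) <- c("lead_ld", "data.frame")
  out
}

#' Match association markers into an LD genotype panel
#'
#' Exact (chrom, pos) matching only — no fuzzy windows — used to anchor
#' linking lines when the LD panel differs from the association panel.
#'
#' @param assoc an `association_table`.
#' @param ld_gt a [genotype_matrix] (the LD panel).
#' @return An integer vector, one element per association row: the index of
#'   the matching marker in `ld_gt$markers`, or `NA` if unmatched; attribute
#'   `n_unmatched` counts the misses.
#' @export
match_markers <- function(assoc, ld_gt) {
  key_a <- paste(assoc$chrom, assoc$pos, sep = ":")
  key_g <- paste(ld_gt$markers$chrom, ld_gt$markers$pos, sep = ":")
  m <- match(key_a, key_g)
  names(m) <- assoc$marker
  attr(m, "n_unmatched") <- sum(is.na(m))
  m
}

#' Export LD results as a tab-separated table
#'
#' @param ld an `ld_matrix` or `lead_ld` object.
#' @param path output path.
#' @return `path`, invisibly. Columns: markerA, markerB, chromA, posA,
#'   chromB, posB, r2, Dprime, n; floats at 6 decimals; an empty input yields
#'   a header-only file.
#' @export
write_ld_table <- function(ld, path) {
  if (inherits(ld, "ld_matrix")) {
    mk <- ld$markers; p <- ld$pairs
    df <- data.frame(markerA = mk$name[p$i], markerB = mk$name[p$j],
                     chromA = mk$chrom[p$i], posA = mk$pos[p$i],
                     chromB = mk$chrom[p$j], posB = mk$pos[p$j],
                     r2 = p$r2, Dprime = p$Dprime, n = p$n_used)
  } else if (inherits(ld, "lead_ld")) {
    lead <- attr(ld, "lead")
    df <- data.frame(markerA = lead$name, markerB = ld$name,
                     chromA = lead$chrom, posA = lead$pos,
                     chromB = ld$chrom, posB = ld$pos,
                     r2 = ld$r2, Dprime = ld$Dprime, n = ld$n_used)
  } else usage_error("ld must be an ld_matrix or lead_ld object")
  df$r2 <- sprintf("%.6f", df$r2)
  df$Dprime <- sprintf("%.6f", df$Dprime)
  df$r2[df$r2 == "NA"] <- "NA"; df$Dprime[df$Dprime == "NA"] <- "NA"
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write LD table: %s", path))
  invisible(path)
}
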