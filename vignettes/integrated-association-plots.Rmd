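---
title: "Methods: LD estimation, layout rules, and the synthetic-data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD estimation, layout rules, and the synthetic-data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldassoc)
```

`ldassoc` aligns three views of a GWAS locus — the association scatter, the
gene models, and the pairwise-LD triangle — in one deterministic figure.
This vignette documents the statistical model behind the LD estimates, the
layout conventions, the synthetic-data generator, and the numerical and
design decisions a maintainer would want to know about.

## EM haplotype-frequency estimation

### Model

For two biallelic loci, unphased diploid data reduce to a 3×3 table of
genotype counts $n_{g_1 g_2}$, where $g$ is the dosage of one designated
allele (we use the empirically minor allele; all LD measures are invariant
to the labeling). Under Hardy–Weinberg equilibrium and random union of
gametes, genotype probabilities are products of the four haplotype
frequencies $(p_{AB}, p_{Ab}, p_{aB}, p_{ab})$; every cell except the double
heterozygote determines its two haplotypes, and the double heterozygote is a
mixture of the coupling ($AB/ab$) and repulsion ($Ab/aB$) phases. The EM
algorithm alternates:

- **E step**: split the $n_{11}$ double heterozygotes between phases with
  weight $w = p_{AB} p_{ab} / (p_{AB} p_{ab} + p_{Ab} p_{aB})$;
- **M step**: set each haplotype frequency to its expected count over
  $2 n$ gametes.

Only samples non-missing at *both* loci enter the table
(pairwise-complete deletion — the simplest defensible policy for scattered
missingness; no imputation is attempted). If either locus is monomorphic
among the used samples the pair is flagged `monomorphic`; if no samples
overlap, `insufficient_data`. Flagged pairs carry `NA` measures and are
never raised as errors, so one bad marker cannot abort a matrix.

### Convergence and multi-start

Iteration stops when the largest absolute frequency change falls below
1e-8, or at 1000 iterations (`iterations == 1000` in the result flags the
cap). The M step preserves the observed allele margins, so the search is
effectively one-dimensional in $p_{AB}$ over its Fréchet interval
$[\max(0, p_A + p_B - 1),\ \min(p_A, p_B)]$.

A single start at linkage equilibrium ($p_{AB} = p_A p_B$) is the
conventional choice, but it is a *stationary point* of the EM map for some
degenerate tables — a table consisting only of double heterozygotes leaves
EM frozen at the saddle $p_{AB} = 0.25$ while the likelihood is maximized at
either boundary. The engine therefore runs three deterministic starts
(linkage equilibrium, near-coupling, near-repulsion — the latter two at 98%
of the corresponding Fréchet bound) and keeps the run with the highest final
log-likelihood, the earliest start winning ties. Results remain fully
deterministic, and the per-iteration log-likelihood trace of the winning run
is exposed (`loglik_trace`) and is non-decreasing, as EM guarantees.

Tables with exactly symmetric counts can have *two* global maxima with
identical likelihoods (coupling and repulsion solutions); the maximizer is
then genuinely non-unique and either answer is correct. The test suite
verifies, by exhaustive enumeration of all 5004 genotype tables with at most
6 samples against an independent grid + golden-section maximizer of the same
profile likelihood, that EM attains the maximum likelihood everywhere and
matches the maximizing frequencies to 1e-4 wherever that maximizer is
unique.

### LD measures

From the estimated frequencies: $D = p_{AB} - p_A p_B$,
$r^2 = D^2 / (p_A p_a p_B p_b)$, and $D' = D / D_{max}$ with
$D_{max} = \min(p_A p_b, p_a p_B)$ for $D > 0$ and
$\min(p_A p_B, p_a p_b)$ for $D < 0$. $D'$ is reported as $|D'|$ — the
heatmap convention; the signed $D$ is kept in the results for anyone who
needs phase direction. The estimator is the package's own EM rather than a
wrapper around a third-party LD library, so the values are reproducible from
the definitions above alone.

## Scope resolution and the lead SNP

Windows are closed intervals in 1-based coordinates; a marker exactly on a
boundary is in, and a gene overlapping the window by a single basepair is
drawn. Transcript windows extend the span by `up` basepairs on the 5′ side
and `down` on the 3′ side, *strand-aware*: for a minus-strand transcript
`up` extends the genomic right edge. That matches the main use of flanks —
pulling promoter-region markers into view.

The lead SNP is the user-designated marker if given, otherwise the smallest
p-value; ties break to the smallest position, then the lexically smallest
name, so a permutation of input rows can never change the figure. The
significance rule is inclusive ($-\log_{10} p \ge$ threshold), chosen so a
marker printed as exactly hitting the threshold is marked significant.
Linking lines default to the full significant set; `link2gene` and
`link2LD` independently override which markers get the scatter-to-gene and
gene-to-LD segments.

## Figure geometry

All layout is computed into a `figure_spec` before any drawing happens;
rendering only replays it. There is no randomness anywhere in layout, so the
same inputs give byte-identical vector output.

- **x mapping.** The scatter and gene layers use genomic coordinates
  normalized to [0, 1]. The LD layer uses *equal index spacing* (the
  Haploview convention): marker $k$ of $n$ sits at $(k + 1/2)/n$. The
  linking lines absorb the genomic-to-index distortion — that bend is what
  makes them informative.
- **Triangle cells.** Pair $(i, j)$, $i < j$, is a diamond centered at
  $x = (i+j)/2$, $y = y_0 - (j-i)/2$ in index units with half-diagonal 1/2.
  Rotating 45° maps the centers onto the integer grid $(i, j)$, which is the
  one-line proof that cells tile the triangle without overlap; the tests
  check it numerically for all $n \le 30$.
- **Colors.** LD values fall into five bins with upper bounds 0.2 … 1.0; a
  value belongs to the first bin whose upper bound is ≥ the value, and 0
  belongs to the first bin. Changing the palette never changes bin
  membership. Pairs without a value (monomorphic, unmatched) use a neutral
  `na_color`.
- **Gene track.** In regional mode, overlapping genes are stacked into lanes
  greedily by start position; each gene is an arrowed line whose arrow sits
  at the 3′ end. In genic mode the transcript is drawn to genomic scale:
  CDS as tall boxes, exons mid-height, UTRs thin, introns as connector
  lines.
- **Labels.** The lead-SNP label (and any highlight labels) are separated by
  a deterministic vertical repulsion with a fixed iteration count — no
  force-directed randomness.
- **Scatter coloring.** Points are colored by $r^2$ with the lead using the
  same five-bin scale, and only when the lead-SNP layer is enabled
  (`leadsnp = TRUE`); with `leadsnp = FALSE` the scatter is neutral. Markers
  missing from the genotype panel are drawn in the `na_color`.

Cross-panel mode (`hapmap_ld`) matches association markers into the LD
panel by exact (chromosome, position) only. A fuzzy window would silently
link wrong markers; an unmatched marker instead keeps its scatter-to-gene
segment and is counted in the run report.

## The synthetic-data generator

`simulate_genotypes()` draws $2 n_{samples}$ haplotypes in independent
blocks. Within a block, each haplotype either copies a single shared latent
uniform draw (probability $t$) or draws per-locus independent uniforms
(probability $1 - t$), thresholded at each marker's allele frequency. Both
components preserve the marginal allele frequencies, so for any within-block
pair $p_{AB} = t\,\min(p_A, p_B) + (1-t)\,p_A p_B$, i.e. $D = t\,D_{max}$:
the population $|D'|$ equals the target $t$ *exactly*, for any
allele-frequency pair, while between-block pairs are exactly independent.
This gives direct control of the LD structure without an external coalescent
simulator. Haplotypes are paired randomly into unphased diploids, and
dosages are recoded to the empirically minor allele so a write/read round
trip through the HapMap format is exact.

`simulate_association()` builds a phenotype as `effect × dosage(causal) +
N(0, 1)` and tests every marker by simple linear regression (the p-values
are exact t-tail probabilities, hence exactly uniform under `effect = 0`).
`toy_gtf()` lays out non-overlapping 2–6-exon gene models with CDS inside
exons, UTRs at the ends, and alternating strands. Seeds are mandatory
everywhere; there is no hidden global random state.

What the generator does *not* emulate: population structure and relatedness,
allele-frequency spectra from real demography, genotyping error,
LD decay with distance within a block (within-block LD is exchangeable), or
multi-chromosome genomes. Tests passing on these fixtures validate the
estimators and the plumbing, not robustness to confounding in real panels —
the association test in particular is a plain marginal regression with no
structure correction.

## Test and verification sizes

The suite checks the EM against brute-force maximization on all tables with
≤ 6 samples; $|D'|$ recovery at targets {0.4, 0.8, 1.0} with 12 replicate
panels of 500 samples each (compared within 3 Monte-Carlo SE of a single
replicate's estimate — the spread across replicates — with a 1e-6 numerical
floor for the degenerate target 1.0, where every estimate is exactly 1);
cross-block independence at 5000 samples; null uniformity over 500
independent markers and power over 100 phenotype replicates; and the
pair-count identity $\binom{2355}{2} = 2{,}771{,}835$ on a full simulated
panel of 2355 markers × 104 samples. These sizes keep the full suite at a
few minutes on one CPU while leaving the Monte-Carlo tolerances meaningful.

## Known limitations

- Genotype input is HapMap text only (two-letter or IUPAC calls); VCF/PLINK
  users should export to HapMap first.
- LD is biallelic-only; markers with more than two observed alleles are
  dropped at load (and counted in the load report).
- The EM assumes Hardy–Weinberg proportions and random mating; inbred or
  structured panels bias haplotype-frequency estimates, as with any
  unphased-genotype LD estimator.
- The triangle layer renders every pair as a polygon; beyond ~2000 markers
  the figure remains correct but raster output is the sensible choice and
  drawing time is dominated by the graphics device.
- One region, one chromosome per figure; no genome-wide Manhattan mode, no
  recombination-rate overlay.
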