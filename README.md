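# ldassoc

Integrated regional association plots with gene structure and linkage
disequilibrium.

After a genome-wide association study (GWAS), making sense of a hit region
usually takes three tools: one to plot the regional association signal, one
to draw the genes under it, and one (Haploview-style) to show the linkage
disequilibrium (LD) structure — followed by manual figure assembly. `ldassoc`
produces the combined figure in one call: an aligned three-layer panel with

1. an **association scatter** of −log₁₀(*P*) against position, with the lead
   SNP enlarged and labeled and every other marker colored by its LD (r²)
   with the lead,
2. a **gene track** — arrowed gene spans for a chromosome window, or the full
   exon/CDS/UTR structure of one transcript, and
3. a **triangle LD heatmap** of all pairwise r² (or |D′|) values in the
   window, drawn as 45°-rotated diamond cells at equal marker spacing,

plus **linking lines** that carry each significant marker from its genomic
position in the scatter, through the gene track, to its index position in
the LD matrix. The LD panel may come from a *different* genotype set than
the association scan (e.g. association from RNA-seq markers, LD from
whole-genome resequencing); markers are matched across panels by exact
(chromosome, position), and markers absent from the LD panel keep their
scatter-to-gene line but stop at the gene track.

It is aimed at quantitative geneticists who have TASSEL/GAPIT-style
association output, a HapMap-format genotype panel, and a GTF annotation,
and want a publication-ready locus figure without manual compositing.

## The statistics underneath

For two biallelic loci with haplotype frequencies
*p*<sub>AB</sub>, *p*<sub>Ab</sub>, *p*<sub>aB</sub>, *p*<sub>ab</sub> and
allele frequencies *p*<sub>A</sub> = *p*<sub>AB</sub> + *p*<sub>Ab</sub>,
*p*<sub>B</sub> = *p*<sub>AB</sub> + *p*<sub>aB</sub>:

- D = *p*<sub>AB</sub> − *p*<sub>A</sub>·*p*<sub>B</sub>
- r² = D² / (*p*<sub>A</sub> *p*<sub>a</sub> *p*<sub>B</sub> *p*<sub>b</sub>)
- D′ = D / D<sub>max</sub>, with D<sub>max</sub> =
  min(*p*<sub>A</sub>*p*<sub>b</sub>, *p*<sub>a</sub>*p*<sub>B</sub>) when
  D > 0 and min(*p*<sub>A</sub>*p*<sub>B</sub>, *p*<sub>a</sub>*p*<sub>b</sub>)
  when D < 0; reported as |D′|.

Haplotype frequencies are not observed in unphased diploid data: the double
heterozygote is phase-ambiguous. `ldassoc` estimates them by
expectation–maximization over the 3×3 genotype-count table (Hill-type EM
under Hardy–Weinberg and random pairing), using only samples non-missing at
both loci. The EM engine is vectorized across marker pairs, so a full
triangle matrix over thousands of markers (millions of pairs) runs in
seconds to minutes without compiled code. A seeded haplotype-block simulator
with an exactly calibrated target |D′| generates HapMap/GTF/association
fixtures, so the whole pipeline is testable offline.

Coordinates are 1-based, fully closed intervals (GTF convention) throughout.

## Worked example

Everything below is simulated, so it runs anywhere:

```r
library(ldassoc)

region <- region_spec("9", 94178074 - 200000, 94178074 + 200000)  # 400 kbp
gt <- simulate_genotypes(
  block_spec(n_blocks = 10, markers_per_block = 10,
             within_block_Dprime = 0.8, maf_range = c(0.15, 0.5),
             n_samples = 150, seed = 42),
  region)
assoc <- simulate_association(gt, causal = "mk05_050", effect = 1, seed = 43)
ann <- toy_gtf(region, n_genes = 6, seed = 44)

gt
#> genotype_matrix: 100 markers x 150 samples
#>   chrom 9, pos 93,978,176..94,369,555
#>   load report: 100 input, 100 retained, 0 dropped

# pairwise LD of two neighboring markers, estimated by EM
f <- em_haplotype_freqs(gt$dosage[49, ], gt$dosage[50, ])
f
#> hap_freqs [ok] n=150 iters=12
#>   pAB=0.335064 pAb=0.114936 paB=0.044936 pab=0.505064  loglik=-258.6959
ld_pair(f)
#> ld_result [ok] D=0.1641 |D'|=0.785 r2=0.4616

res <- regional_plot(chr = "9", left = region$left, right = region$right,
                     gtf = ann, association = assoc, hapmap = gt,
                     threshold = 5, out = "example.png",
                     style = plot_style(leadsnp_size = 2))
#> markers: 100 loaded (0 dropped at load) in genotype panel
#> LD: 100 markers in window, 4950 pairs computed
#> linking: 0 association marker(s) unmatched in the LD panel
#> scope: 100 association markers, lead SNP mk05_050, 5 significant
```

The run report reads: all 100 simulated markers parsed; the triangle layer
holds 100·99/2 = 4950 pairwise LD cells; the most significant marker
(`mk05_050`, the simulated causal variant) became the lead SNP; five markers
cleared −log₁₀(*P*) ≥ 5 and get linking lines. `res$spec` is the full,
deterministic figure geometry; `res$ld$pairs` and `res$lead_ld` hold the
numbers behind the heatmap and the scatter coloring.

For one gene instead of a window (flanks are strand-aware, 5′/3′):

```r
genic_plot("GENE3_T01", ann, assoc, gt, threshold = 5,
           up = 500, down = 600, out = "genic.svg")
```

## Command line

Each plotting argument has a kebab-case flag; `ldassoc <subcommand> --help`
lists them all. The four subcommands, on files produced by
`ldassoc simulate`:

```sh
Rscript exec/ldassoc simulate --out-prefix fx --seed 17
# regional figure: lead-SNP LD + triangle LD + gene arrows + linking lines
Rscript exec/ldassoc regional --chr 9 --left 93978074 --right 94378074 \
    --gtf fx.gtf --association fx_assoc.tsv --hapmap fx.hmp.txt \
    --threshold 5 --leadsnp-size 2 --out fig.png
# custom five-bin gray color scale
Rscript exec/ldassoc regional ... --color02 gray81 --color04 gray61 \
    --color06 gray41 --color08 gray11 --color10 gray1 --out fig_gray.png
# triangle LD from a second genotype panel
Rscript exec/ldassoc regional ... --hapmap-ld other_panel.hmp.txt --out fig_ld2.png
# zoom by shrinking the window
Rscript exec/ldassoc regional --chr 9 --left 94176074 --right 94184074 ... --out zoom.png
# single-gene figure with transcript structure, no lead-SNP coloring
Rscript exec/ldassoc genic --transcript GENE3_T01 --leadsnp false \
    --triangle-ld true --threshold 8 ... --out gene.png
# flanking sequence, highlighting, and explicit link selections
Rscript exec/ldassoc genic ... --up 500 --down 600 --out gene_flanks.png
Rscript exec/ldassoc genic ... --up 500 --down 600 \
    --marker2highlight highlight.tsv --out gene_hi.png
Rscript exec/ldassoc genic ... --marker2highlight highlight.tsv \
    --link2gene mk1,mk2 --link2ld mk1,mk2 --out gene_links.png
# pairwise LD as a table
Rscript exec/ldassoc ld-export --hapmap fx.hmp.txt --out ld.tsv
```

Exit codes: 0 ok, 2 usage, 3 input format, 4 empty scope, 5 I/O.

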