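---
title: "Models and methods behind crisprmat"
author: "crisprmat maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprmat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crisprmat` reimplements, as tested R code on synthetic data, the
computational layers of an in vivo pooled CRISPR knockout screen for
cardiomyocyte-maturation regulators and of the epigenome–transcriptome
analysis that links H2B monoubiquitination (H2Bub1) dynamics to
maturational gene expression. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices made
where the design was genuinely open. Every empirical claim below is one
the test suite or `scripts/acceptance.R` computes.

## Guide library design

For each gene, every 20-nt protospacer adjacent to an NGG PAM (either
strand) whose blunt cut — between protospacer positions 17 and 18,
i.e. 3 bp 5′ of the PAM — falls inside exonic coding sequence is a
candidate. Candidates are annotated with:

* **CDS percent** — `100 ×` (coding bases strictly 5′ of the cut in
  translation order) / (total CDS length), evaluated at the cut site on
  the longest-CDS transcript containing it. Early cuts (5–50%)
  truncate most of the protein; cuts past 80% often leave functional
  products.
* **Constitutivity** — whether the cut lies in sequence exonic in
  *every* isoform (interval intersection of the transcripts' exon
  sets), so the lesion cannot be spliced around.
* **Off-target profile `(n0, n1, n2)`** — counts of genomic NGG sites
  matching the spacer with 0, 1, 2 mismatches over the 20 protospacer
  bases. The on-target site is included in `n0`, so a uniquely mapping
  spacer reports `(1, 0, 0)`. Genomic `N` bases never match
  (conservative). The scan is a small compiled kernel with early exit;
  tests pin it to a naive full-genome scan on genomes up to ~1 Mb.
* **Out-of-frame score** — a microhomology-mediated end-joining
  predictor in `[0, 100]`. All repeated ≥2-mers flanking the cut are
  enumerated; a pattern at left offset `i` and right offset `j` implies
  a deletion of `j − i` bases and scores
  `100 · exp(−(j−i)/20) · (AT + 2·GC)` over the pattern bases; patterns
  contained in a longer pattern implying the same deletion are
  duplicates. The score is the percentage of total pattern weight on
  deletions whose length is not a multiple of 3. The scoring window is
  30 nt per side (the typical context length of microhomology design
  tools; windows truncated at contig edges carry a flag). The score is
  invariant under reverse complementation, which the suite checks
  property-style.

Selection applies five rules in order, each only while fewer than six
guides are held: (1) constitutive, CDS 5–50%, profile `1,0,0`,
out-of-frame > 60; (2) constitutive, CDS 5–80%, `1,N,N`, > 60; (3) any
exon, CDS 5–80%, `1,N,N`, > 60; (4) any exon, CDS 5–80%, `N,N,N`,
> 60; (5) any exon, any CDS, `N,N,N`, any score. Within a tier the
order is out-of-frame score descending, CDS percent ascending, then
genomic coordinate — preferring frameshift-prone, 5′-biased cuts and
making selection deterministic. Genes exhausting tier 5 are flagged
undesignable.

Each selected spacer becomes one 80-nt synthesis oligo: a 5′ G is
prepended when the spacer does not already start with G (the U6
promoter initiates efficiently on G; prepending unconditionally would
make every insert 21 nt, and we prefer to leave native G-starting
20-mers untouched — the oligo geometry absorbs either length), and the
insert is flanked by opposed SapI cassettes with fixed PCR handles so
that simulated digestion (`sapI_digest()`) releases exactly the
G-extended spacer. Spacers containing a SapI recognition site would
self-cleave and are rejected before selection. Seven non-targeting
control spacers — random 20-mers verified to have zero 0/1/2-mismatch
NGG sites in the design genome, synthetic stand-ins for cross-species
controls — complete the library.

Coordinates are 1-based inclusive throughout the package, the native
convention of R and Bioconductor (`IRanges`); GTF I/O is 1-based
inclusive and BED export converts to 0-based half-open.

## Screen deconvolution and QC

Reads are trimmed by anchoring the 5′ adapter and the 3′ scaffold
(each with at most one mismatch) and taking the last 20 nt of the
variable region between them — which also strips the cloning G from
21-nt inserts. Counting is an exact match against the designed
20-mers: for uniquely designed spacers this is equivalent to aligning
reads and counting coverage of guide loci, without an aligner
dependency. Reads in = assigned + unassigned + discarded, per sample.

Sample QC mirrors the three exclusion criteria used for pooled sorted
screens, with declared numeric defaults where the criteria are
qualitative: a sorted sample fails *control enrichment* when the
spiked positive-control guides' log2 enrichment over the mean input
abundance is below 1; any sample fails *clustering* when its mean
Pearson correlation (on `log1p` median-of-ratios-normalized counts)
with its own role group does not exceed its mean correlation with the
other role group; any sample fails *coverage* when under 50% of
library guides are detected. All three thresholds are exposed.

## Guide-level statistics: the NB-Wald core

Counts are normalized by median-of-ratios size factors (per sample,
the median over all-nonzero guide rows of count / geometric mean
across samples; a ≥90%-nonzero fallback covers sparse tables). The
per-guide model is negative binomial, `var = μ + α μ²`, with sample
role as the single covariate and log size factors as offsets.
Dispersion is estimated per guide by method of moments on the
normalized counts, shrunk 50/50 on the log scale toward a log-linear
mean–dispersion trend and floored at 1e-8 — enough stabilization for
25-sample screens without the full empirical-Bayes machinery; Cook's
filtering, LFC shrinkage and independent filtering are deliberately
out of scope. The GLM is fit by a vectorized IRLS with a tiny ridge
(1e-6) so one-group-zero guides converge to large finite estimates;
no pseudocounts are added, and guides with zero counts everywhere are
flagged and excluded from the BH denominator. The Wald statistic
log2fc/se is compared with the standard normal; two-sided p-values are
BH-corrected.

Because normalization is relative, multiplying one library's counts by
a constant changes all normalized counts by a common factor
`c^(1/n)`; fold-changes, Wald statistics and significance calls are
invariant up to the tiny dispersion-plug-in effect of that factor
(the suite asserts agreement to 0.02 log2 units), and ChIP signals
below are pinned up to one common positive constant. The suite also
cross-checks size factors and Wald results against DESeq2 on the same
matrices — as an independent reference, never as the implementation.

Calibration: on a null screen (1,000 guides, 14 input vs 11 sorted,
α = 0.1) the type-I error at nominal 0.05 must land in [0.03, 0.07].

## Gene-level aggregation: α-restricted robust rank aggregation

Guides are ranked by one-sided p (from the signed Wald statistic) in
the chosen direction; non-targeting guides stay in the ranking but
receive no gene score. For a gene with *n* guides of which *j* are
significant at `alpha_p`, the score is
`ρ = min_{k ≤ j} P(Beta(k, n−k+1) ≤ r_(k))` over its sorted
normalized ranks, and the gene p-value is the fraction of
guide-to-gene permutations (preserving guides-per-gene counts, seeded)
reaching a ρ at least as small — or exact enumeration of all guide
subsets on small instances, which the suite compares against an
independent oracle using the binomial-sum identity for the Beta tail.
Gene ranks break permutation-floor ties by ρ, then gene id. The null
uniformity check runs with `alpha_p = 1` (every guide contributes):
with a strict α under the null almost every gene has ρ = 1 and the
p-distribution is degenerate by construction, so uniformity is only
diagnostic when the α restriction is disabled.

## ChIP quantification, one scheme per mark

* **H2Bub1 (gene body)** — median-of-ratios normalization across ChIP
  and input libraries, division by gene length (first TSS to last
  TSE), replicate averaging per stage, then subtraction of the
  identically processed input; a gene is occupied where signal > 0.
  Negative signals are kept (no clipping) so stage deltas stay linear.
  Input subtraction happens after replicate averaging, applied
  uniformly to both marks that use input. Note a structural property
  of this scheme: since median-of-ratios centres the median
  enrichment ratio, the occupancy call splits genes at the median
  chip/input ratio — meaningful when the gene universe is bimodal
  (marked vs silent genes), which is how the synthetic generator is
  built (see below).
* **H3K4me3 (TSS ± 1 kb)** — the maximum per-base coverage in each
  window on the RPKM scale (`cov · 1e9 / library size` for a 1-bp
  bin), replicate-averaged, input-subtracted; only the
  highest-scoring TSS is kept per gene, and genes are retained above
  a 500-RPKM floor.
* **H3K36me3 (gene body)** — RPKM over the gene body
  (`count · 1e9 / (library size · length)`), replicates averaged, and
  the retained set is the top quintile by the stage-averaged score
  with a deterministic tie-break by gene id.

## Integration layer

Maturational (adult vs neonatal) and knockout (KO vs control)
differential expression reuse the NB-Wald core. The adult- and
neonatal-specific gene sets are the top and bottom 100 genes by
maturational log2 ratio (ties broken by gene id). Preranked GSEA uses
the weighted running-sum statistic with weight exponent 1, gene-label
permutations, nominal p among same-sign permutations, NES against the
same-sign mean |ES|, and a 30-gene set-size floor (waivable only for
tiny oracle instances); the running-sum extremum is evaluated only at
hit-adjacent positions, which equals the full position-by-position
sum (asserted against a brute-force oracle).

Quadrant classification restricts to genes responsive to RNF20/40
loss — |KO log2fc| > 1 *and* adjusted p < 0.05, both configurable;
the p cut implements "differentially expressed" since a fold-change
filter alone would admit noisy low-count genes — and labels genes by
the joint sign of maturational ΔRNA and ΔH2Bub1 (UR both positive, LL
both negative). For each focal quadrant the 2×2 table of KO-down (and
KO-up) calls inside vs outside the quadrant is tested by the exact
hypergeometric (Fisher) test; the two-sided p sums probabilities of
tables no more probable than observed, and both one-sided tails are
reported because figure-level tests of this kind often do not state
sidedness. Odds ratios use the Haldane 0.5 correction when a cell is
zero. Binned summaries of ΔH2Bub1 against ΔRNA use left-open
right-closed bins and box-and-whisker statistics (median, quartiles,
most extreme observations within quartile ± 1.5 IQR).

## The synthetic-data generator

One root seed with per-artifact child streams (genome, truth, screen,
chip, rna, reads) makes every output byte reproducible and keeps
artifacts independent: adding one never perturbs another.

* **Genome/annotation** — uniform-composition sequence; non-overlapping
  genes on alternating strands, ≥1 kb apart; 3–5 exons of width
  divisible by 3 whose union is the CDS; extra isoforms skip one
  internal exon, and the first gene always has ≥2 isoforms so
  constitutive-exon logic is exercised.
* **Screen counts** — NB draws (`var = μ + α μ²`, shared α, default
  0.1) around per-guide expected proportions of a 10⁶-read depth.
  Defaults encode the screen's study conditions for recovery tests:
  500 genes, 50 hits at log2fc 3, per-guide effect heterogeneity
  N(0, 0.5) (which makes rank aggregation non-trivial), 15 input and
  15 sorted samples. A spiked positive-control gene enters at low
  input abundance with effect `hit_log2fc + 2` on each guide,
  emulating a co-packaged control virus. Because sorted proportions
  renormalize, the bulk of unaffected guides carries a small
  compositional shift that median-of-ratios normalization removes —
  deliberately, as in real sorted screens. Screen reads can be
  emitted as FASTQ (adapter + G-extended spacer + scaffold, with a
  corrupted fraction) to exercise trimming; ChIP and RNA data are
  simulated directly as counts.
* **Multi-omics** — per-gene true (ΔH2Bub1, ΔRNA) pairs are bivariate
  normal with correlation `chip_rna_coupling` (default 0.4); the
  dynamic-ChIP set is the top `frac_dynamic_chip` by |ΔH2Bub1|.
  Under `oppose_maturation`, the true KO effect is
  `−0.8·ΔRNA + N(0, 0.4)`, planting the upper-right-quadrant
  KO-down enrichment. H2Bub1-marked genes sit well above the input
  background while unmarked gene bodies are depleted relative to
  input (ChIP reads concentrate at marked loci), and the marked
  fraction defaults to 0.5: the H2Bub1 scheme calls occupancy at the
  median enrichment ratio, so a bimodal, roughly half-marked universe
  is the regime in which the printed scheme recovers a planted
  occupancy structure — matching real gene universes that include
  silent genes. H3K4me3 promoter strengths are log-normal, calibrated
  so ~20% of genes clear the 500-RPKM floor at a 2·10⁷-read library
  (~7,000 of 35,000 genes).

What the generator does **not** emulate: sequence composition bias
(GC, mappability), read-level ChIP/RNA noise, isoform-level
expression, batch structure, or the biological effect-size
distribution of the real screen — the configured effects are planted
conditions for parameter-recovery tests, not estimates of the
biology. Passing tests therefore demonstrate that the implementations
recover what they claim under their stated models, not that the
models capture every property of real libraries.

## Problem sizes and numerical choices

The test suite uses 10-gene / 120-kb genomes for end-to-end design,
≤25-kb genomes for brute-force off-target oracles, 1,000-guide null
screens for calibration, the 500-gene default screen for recovery,
5,000-gene multi-omics simulations for coupling, and one
35,000-gene simulation for the retention-cardinality checks;
permutation counts in tests are 2,000–4,000 (the user-facing default
is 10,000). The planted single-guide recovery example runs at
dispersion 0.01 — technical-replicate-like noise under which the
±0.3 log2fc recovery band is a meaningful check of the estimator
rather than of sampling noise. Dead samples (no counts) receive unit
size factors and fail QC by coverage rather than erroring. All
degenerate paths — empty gene lists, zero reads, all-zero guides,
single-sample roles, windows at contig edges, zero Fisher cells —
return flagged or empty results rather than failing.

## Known limitations

The NB-Wald core intentionally omits DESeq2's outlier and independent
filtering, so borderline guides can differ from a full DESeq2 run;
the RRA permutation p has resolution 1/(n_perm+1); the H2Bub1
occupancy call is only as meaningful as the bimodality of the
enrichment-ratio distribution; and genome-scale (mouse-sized) design
is out of scope — tested genomes are ≤1 Mb synthetic sequences.
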