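---
title: "Models and methods behind acrpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acrpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrpoly)
```

`acrpoly` compares chromatin accessibility, histone-mark context, DNA
methylation and gene expression between a natural allopolyploid (NAC), a
resynthesized allopolyploid (RAC) and an in silico "hybrid" (A_C) built
from the diploid progenitors, on a shared two-subgenome coordinate system.
This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic data generator does and does not
emulate.

## Coordinate model

Every interval is 0-based half-open, BED-style; GFF3 (1-based closed) is
converted at the read/write boundary. A single internal convention removes
an entire class of off-by-one errors; the overlap and merge engines are
backed by IRanges/GenomicRanges behind this interface. The TSS is `start`
for + strand genes and `end − 1` for − strand genes (the last covered
base); the TTS is the symmetric anchor. Overlap thresholds default to 1 bp
everywhere and are configurable.

## The in silico hybrid

The hybrid's purpose is a parental baseline without polyploidization
history. Because the progenitors map to disjoint subgenomes, mixing
processed data is equivalent to mixing reads up to depth scaling, which the
mixer makes explicit:

* **Tracks and peaks (ATAC/ChIP), counts (RNA)** — replicate *i* of each
  parent becomes hybrid replicate *i*. Each parent's values are rescaled so
  both contribute equal effective totals (the 1:1 mix): with totals
  $T_r \ge T_o$ the factors are $T_o/T_r$ and $1$. The hybrid library size
  is the sum of the scaled totals, and the hybrid peak set is the union of
  the parental calls (peaks are not re-called; peak calling is upstream of
  this package).
* **Methylation** — site tables are concatenated and per-site coverage is
  rescaled so total coverage splits across subgenomes in proportion to the
  parental genome sizes. Only the over-represented parent is scaled down,
  coverages are rounded to integers, and each site's methylation level is
  preserved up to rounding (|Δlevel| ≤ 1/coverage).

Restricting any hybrid object to one subgenome therefore reproduces the
corresponding parental object times a known scalar — an identity the test
suite asserts exactly.

## ACR taxonomy

Peaks pass the accessibility filter iff fold enrichment is strictly
greater than 3.4. Two classifications coexist deliberately, because they
answer different questions:

* `genic_flag` uses *any-overlap*: a gACR touches a gene span by ≥ 1 bp.
* `feature` uses the ACR *midpoint* with priority promoter (tiered 0–1,
  1–2, 2–3 kb upstream of the TSS, strand-aware) > 5′/3′ UTR > exon >
  intron > ≤ 300 bp downstream of the TTS > distal intergenic. UTR and
  intron calls are only made when UTR/exon tables are supplied; otherwise
  midpoints inside a gene span report "exon". Ties at equal priority go to
  the nearest TSS; distal ACRs associate with the nearest TSS within a
  10 kb cap (configurable), or with no gene.

Overlap classes for the three genotypes are defined per ACR: common to all
three (≥ 1 bp overlap with at least one ACR in each other genotype),
genotype-specific (overlap with none), otherwise shared two-way. Pileup
deciles sort ascending with ties broken by (chrom, start) for determinism;
when the count is not divisible by 10 the lowest groups take the extra
members. Histone clusters 1–6 are the six single/pairwise combinations of
H3K27me3, H3K4me3 and H3K27ac peak overlap; ACRs with no mark or all three
are reported unassigned rather than forced into a cluster, and flagged as
such in the output.

## Differential enrichment (DEA)

For a genotype pair, overlapping peak calls from both genotypes are merged
into one tested region. Per replicate, signal is the track value summed
over the region, divided by the library's mapped-read total (per million).
The statistic is a two-sided **pooled-variance t test on log2(signal + 1)**
with `n_x + n_y − 2` df; a region is differentially enriched iff
|log2FC| ≥ 1 (ratio of group means) and p < 0.05. The pooled t was chosen
over the Welch variant after measurement: at 3 replicates per side the
Welch df correction is noticeably conservative (empirical type-I 0.036 at
nominal 0.05 over 50 000 null features), while the pooled t is calibrated
(0.050); after the log transform of depth-normalized signal the
equal-variance assumption the pooled t needs is mild. Degenerate inputs
follow two explicit rules: regions with zero signal in every replicate of
both groups are `not_tested`, and zero-variance groups with different
means are treated as perfect separation (p = 0; identical constants give
p = 1) so that noise-free data remain classifiable.

## Differential expression (DEG)

Counts are normalized with joint median-of-ratios size factors (computed
over genes expressed in every sample). Per gene, an NB dispersion
$\alpha$ (variance $\mu + \alpha\mu^2$) is estimated by pooled
within-group method of moments, then **moderated by flooring it at the
genome-wide median** of the expressed genes' estimates. The log mean ratio
is tested with a Wald statistic using the delta-method standard error
$\sqrt{(1/\mu_x + \alpha)/n_x + (1/\mu_y + \alpha)/n_y}$ against a
standard normal, and p-values are BH-adjusted; DEGs satisfy |log2FC| ≥ 1
and padj ≤ 0.001. The moderation is the load-bearing choice: with 3
replicates, raw per-gene moment estimates make the normal-reference Wald
test anticonservative (measured type-I 0.116), while a t(4) reference is
calibrated but cannot reach padj ≤ 0.001 for even 8-fold changes (its
tails are too heavy for small p). Flooring the dispersion at the central
tendency of its genome-wide distribution removes the genes whose variance
was underestimated by chance — the source of the inflation — and restores
both calibration (measured 0.050) and power (> 0.99 for planted 8-fold
changes at dispersion 0.05). The same moderation is applied to the
homeolog-bias (BEG) test: per pair, per-replicate log2 ratios of the A to
the C copy (+0.5 pseudocount) are tested with the pair's standard
deviation floored at the across-pairs median, normal reference, BH across
pairs; A-BEG iff log2FC ≥ 1 and padj ≤ 0.05, C-BEG symmetric. Those BEG
thresholds are package defaults, exposed in the configuration.

## Methylation

The site level is methylated reads over coverage; sites with coverage
below 3 are missing data and excluded from *every* downstream sum. The
region level is $\sum m_i / \sum c_i$ over qualifying sites — weighted by
coverage, never a mean of site levels — and a region with no qualifying
site is reported missing, never 0. Profiles around anchors pool counts per
bin across anchors (strand-aware), so bins are themselves weighted levels.
Symmetric CG sites are kept strand-separate; no CpG-pair collapsing is
performed.

## Profiles and replicate QC

Meta-profile matrices support reference-point (TSS or peak center) and
scale-regions modes; bin values are mean per-base coverage converted to
RPKM as $\mathrm{cov} \times 10^9 / (1000 \times \mathrm{mapped\ reads})$,
minus-strand rows flipped so column 1 is biologically upstream,
out-of-chromosome bins contributing 0. Defaults are ±1 kb flanks at 10 bp
bins. Replicate QC bins the genome (default 1 kb) and reports pairwise
Spearman correlations with average ranks for ties.

## Rank-sum comparisons

Subgenome asymmetry comparisons use the two-sided Wilcoxon rank-sum test:
exact by full enumeration of all $\binom{n_x+n_y}{n_x}$ assignments
(midranks under ties) when both sides have ≤ 8 observations, and otherwise
a large-sample approximation with tie-corrected variance, continuity
correction, and an Edgeworth term using the exact null excess kurtosis
$-\tfrac{6}{5}(n_x^2+n_y^2+n_xn_y+n_x+n_y)/(n_xn_y(N+1))$. The kurtosis
term matters at the boundary: the plain corrected-normal approximation can
differ from the exact p by ~0.011 at 8 vs 8, while the Edgeworth-corrected
version stays within ~6×10⁻⁴ (verified against enumeration over 2000
random instances). Chi-square comparisons use the Pearson statistic
without continuity correction; all tests are two-sided, and the asymmetry
report applies no multiple-testing correction across its rows (stated in
the output header's documentation).

## The synthetic data generator

The generator emulates the *structure* the analyses assume, with known
truth: a two-subgenome genome (default 2 × 1 Mb per subgenome), 60
homeolog pairs plus 40 unique genes per subgenome with duplicate classes
in configurable proportions; 300 ACR loci per genotype — 30% common to
all three genotypes, 20% common with a planted 2-log2 differential in one
genotype, 50% genotype-specific — 30% of loci anchored 100 bp upstream of
a gene TSS and the rest intergenic, plus 10% sub-threshold fold-enrichment
decoys the filter must remove; histone-mark combinations drawn so all six
clusters are populated; coverage tracks as Poisson reads in 100 bp bins
around a slowly varying background profile (log-sd 0.5) shared by a
genotype's replicates — which is what makes replicate rank correlations
informative — with a triangular enrichment kernel over each peak whose
mean equals background × enrichment (default 0.2 × 20); binomial
methylomes at context rates CG 0.60 / CHG 0.30 / CHH 0.08 multiplied by
0.2 inside ACRs, Poisson coverage mean 8 so some sites genuinely fall
under the coverage-3 rule; NB expression (mean 100, dispersion 0.05) with
10% planted DEGs at 3 log2 and 20% of homeolog pairs planted as BEGs at
2 log2. Homeolog partners share their baseline mean, DEG shifts planted on
one copy of a pair are applied to both copies, and silencing only hits
unpaired genes — otherwise planted DEG effects would masquerade as
expression bias and corrupt the BEG truth tables. Progenitor data are
generated directly on the allopolyploid coordinates (each parent covering
only its subgenome), matching the strategy of mapping everything to the
allopolyploid reference. A `noise = "none"` mode emits expected values
instead of draws; under it every classifier must recover its truth table
exactly, which the acceptance tests assert.

What the generator does *not* emulate: sequence composition and
mappability, transposable elements, peak-shape diversity, spatially
correlated replicate noise beyond the shared background profile, and any
genuine subgenome asymmetry (the default design is symmetric, so the
asymmetry report's significant rows measure its false-positive rate).
Passing tests therefore demonstrate correctness of the computations and
calibration of the statistics under the stated models — not robustness to
every artifact of real sequencing data.

## Problem sizes and determinism

Default problem sizes (4 Mb genome, 200 genes, 300 ACRs per genotype,
100 000 cytosines per genotype and replicate, 3 replicates) were chosen so
a full pipeline run completes in well under a minute while every
classifier and test operates far from degeneracy. Calibration checks use
2000 null features at 3 replicates. Everything is driven by a single seed:
each generator stage derives a fixed offset substream, and two runs with
the same configuration are byte-identical down to the output files' md5
sums, which the per-stage JSON manifests record.

## Known limitations

The DEA caller tests merged common regions, so adjacent distinct peaks
that overlap the same partner region are tested as one unit. Hybrid peak
sets inherit parental calls rather than re-calling peaks on mixed signal.
The narrowPeak writer encodes p/q values as −log10, so a read of an
externally produced file round-trips bit-exactly at the file level only
after one write–read cycle. The BEG thresholds stand in for a convention
the upstream literature does not pin down and should be treated as
configuration, not biology.
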