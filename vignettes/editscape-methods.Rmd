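---
title: "editscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{editscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A-to-I RNA editing is the deamination of adenosine to inosine by ADAR
enzymes, read by sequencers as guanosine. Against a reference genome an
edited transcript therefore shows an A→G mismatch (or, for a transcript from
the minus strand observed in an unstranded library, a genomic T→C mismatch).
Editing is quantitative — each site has a level β, the fraction of
transcripts edited — and in neural tissue many sites gain editing as
development proceeds, most prominently recoding sites in ion-channel and
glutamate-receptor genes (the Q/R, I/V, Y/C class of amino-acid changes).
`editscape` is a reusable implementation of the standard analysis: call
sites from aligned reads, quantify levels, annotate, cluster temporal
patterns, relate overall editing to ADAR expression, and quantify per-cell-
type editing from barcoded single-cell alignments.

# The calling cascade

For each sample, reads below the mapping-quality floor are excluded whole;
individual bases below the base-quality floor (and `N` bases) are excluded
from the pileup. At a position with quality-passing coverage $N$ and counts
$(n_A, n_C, n_G, n_T)$:

* a **plus-strand candidate** requires reference A and $n_G \ge 1$, with
  $n_\mathrm{edit} = n_G$, $n_\mathrm{ref} = n_A$;
* a **minus-strand candidate** requires reference T and $n_C \ge 1$, with
  counts complemented ($n_\mathrm{edit} = n_C$, $n_\mathrm{ref} = n_T$) —
  the same A-to-I event seen on the transcribed strand.

A candidate survives iff $N \ge 15$, mismatch rate
$m = n_\mathrm{edit}/N \ge 0.02$, and third-allele fraction
$n_\mathrm{other}/N \le 0.01$. All `>=` thresholds are inclusive exactly as
printed, and the boundary behaviour (14/15, 0.019/0.02, q24/q25, mapq
19/20, 4-of-8/5-of-8) is pinned by tests. Candidates matching a known SNP
(A>G for plus, T>C for minus, same position) are retained with status
`snp_excluded` — the heterozygous-SNP mimic sits near β = 0.5 in every
sample and is exactly what this filter exists to catch. A site becomes
**high-confidence** iff it is a surviving candidate in strictly more than
50% of all samples.

Two statistics are deliberately distinct: the *mismatch rate*
$m = n_\mathrm{edit}/N$ drives the candidate filter (its denominator is all
quality-passing mapped reads), while the *editing level*
$\beta = n_\mathrm{edit}/(n_\mathrm{edit}+n_\mathrm{ref})$ excludes
other-base reads from the denominator. The per-sample *overall editing
level* is $\sum n_\mathrm{edit} / \sum N$ over high-confidence sites with
evidence in that sample; we restrict the denominator to high-confidence
sites because whole-transcriptome read totals are not recoverable from the
pipeline's inputs (an Open Question resolved here and recorded once).

The third-allele guard is this package's explicit, testable version of the
noise rejection the published pipelines delegate to their source method; 1%
of coverage is the default cap. The per-sample filters are required in
*every* counted sample (not just discovery samples); the merged record still
carries evidence — counts and β — from every sample with any coverage, so
downstream matrices see non-qualifying but covered stages as data, not as
holes.

Clonal-read removal (PCR duplicates) keeps the first read per (chromosome,
leftmost position, orientation, CIGAR) key. It is on by default in the
driver and off in the low-level API; the external tools the field uses for
this have their own semantics, so ours are fixed and documented rather than
inferred.

# Coordinates

All user-facing positions are 1-based; internally intervals are 1-based
closed — the IRanges/GenomicRanges convention. The build contract suggested
half-open 0-based internals; in R that would mean fighting every
Bioconductor API this package is built on, so the package adopts the native
convention instead and keeps the observable contract: emitted positions are
1-based, BED input (0-based half-open) is converted on read by rtracklayer,
and converting a position out and back is the identity (tested).

# Annotation

Region assignment uses a fixed precedence when a site overlaps several
annotations: `exonic_cds > utr3 > utr5 > ncRNA > intronic > intergenic`,
ties within a category broken by lexicographic gene id. The precedence
mirrors the default behaviour of precedence-based gene annotators; the
published analysis used such a tool without stating options, so the order
here is a recorded package decision, not an inference. Shuffling gene input
order never changes a call (tested).

Recoding reconstructs the coding-strand codon across CDS junctions using
the annotated frame; minus-strand genes reverse-complement, so a genomic
T→C site is an mRNA A→G. Translation uses the standard codon table (NCBI
table 1, no selenocysteine), and the package's own table is checked
exhaustively against the Biostrings genetic code over all 64 codons × 3
edit offsets × both strands. Stop-codon changes (e.g. TAG→TGG) are labelled
with `*` and count as nonsynonymous.

Repeat overlap returns the innermost (shortest) overlapping interval —
"most specific element" — so a B1 nested in a LINE reports B1. The ±5 bp
context matrix takes the 11-mer on the edited strand (position 0 is A by
construction); sites within 5 bp of a contig end are skipped and counted
rather than padded with invented bases.

Editing-level comparison across repeat classes (B1 vs other-repeat vs
non-repeat) uses a two-sided Wilcoxon rank-sum test implemented in the
package: the exact permutation null is computed by dynamic programming over
untied ranks when both groups have ≤ 12 observations; with ties or larger
groups it falls back to the normal approximation with tie and continuity
correction. The exact path is validated against full enumeration of all
rank assignments.

# Temporal patterns and regression

Missing cells of the sites × stages matrix are imputed with the site mean
*only* on the way into clustering; the matrix object preserves missingness.
Whether the original analysis imputed, dropped or zero-filled is unstated;
mean imputation is the recorded choice and keeps every recovered site in
the clustering.

Clustering is Lloyd's k-means on raw (unscaled) levels — the published
heatmap clusters plain levels — with a `scale_rows` switch for
row-standardization. k = 3 is the pipeline default; `n_init = 10` seeded
restarts keep the lowest within-cluster SSE (a single k-means call is
under-determined). Labels `high`/`medium`/`low` are assigned by descending
centroid grand mean, which makes the label order an invariant rather than
an accident of initialization.

The SSE elbow curve is computed for k = 1…8 with each k warm-started from
the previous solution plus the point farthest from its centre, which makes
the curve provably non-increasing. The suggested k maximizes the second
difference of **log** SSE. The raw-scale second difference was the original
design, but it always fires at the first large drop (k = 2) on any strongly
separated data, contradicting the requirement that planted three-pattern
data suggest k = 3; curvature on the relative scale is the minimal fix and
is scale-invariant. The suggestion is advisory — the default stays k = 3.

ADAR association is per-gene ordinary least squares of overall editing
(response) on FPKM (predictor) across stages, two-sided t-test on the
slope, Benjamini–Hochberg across the gene list. Zero-variance predictors
are flagged rather than tested.

# Pseudobulk single cell

Barcoded reads are partitioned by a barcode → cell-type map (consumed, not
computed: cell clustering and QC belong to the upstream single-cell
analysis). Editing per cell type is quantified only at the bulk
high-confidence *background* sites, with the same quality filters as bulk;
the level here is edited reads over **all** quality-passing mapped reads at
the site — the printed definition for the single-cell arm, deliberately not
the bulk G/(G+A). A site counts as *detected* in a type at coverage ≥ 5 and
edited reads ≥ 2 (the figure behind the per-type detection ratio states no
rule; these defaults are explicit and configurable).

The gene-set module score follows the binned-control construction: genes
ranked by mean expression across cells, cut into 24 equal-frequency bins;
for each set gene, 100 control genes are sampled from its bin (set genes
excluded; with replacement when the bin is smaller); a cell's score is its
mean over set genes minus its mean over the pooled control draws. Scores
are deterministic under the seed.

# The synthetic world

The generator's defaults are the stated study design: 8 ordered stages
(E14.5, E17.5, P0, P3, P7, P10, P14, P21), 60 planted sites (20 per
pattern), 20 heterozygous A/G SNPs, 150 unedited background A positions,
mean coverage 50 (Poisson; negative-binomial behind `overdispersion`), read
length 100, per-base error rate 0.001, and a 120 kb single-contig genome
with 12 two-exon genes on alternating strands. Planted sites are placed so
each compartment exercises one annotation path: nonsynonymous CDS positions
(verified against the codon table at planting time), 3'UTRs, intergenic B1
elements, a few non-B1 repeats, and intergenic non-repeat; all sites are A
on their strand in the emitted FASTA (tested). Sites, SNPs and background
positions keep a 250 bp minimum spacing — beyond twice the read length — so
no read spans two targets and each site's reads are an independent binomial
sample.

Trajectory shapes are the package's own (the source material shows only
heatmap trends): `high` and `medium` are normalized logistics in the stage
index with random start/final levels (final ∈ [0.55, 0.90) and
[0.22, 0.45) respectively — monotone by construction), `low` is a constant
in [0.02, 0.10] with ±0.02 jitter (always < 0.15, range < 0.05). These
ranges are what the pattern-labelling invariants rely on. SNPs show the
alternate allele with probability 0.5 per read in every stage —
stage-constant, the signature the SNP filter keys on. ADAR expression is
affine in the per-stage mean planted level plus Gaussian noise (slope 40,
intercept 5, σ = 1 FPKM); background genes are uncorrelated. The
single-cell matrix gives every cell type's *owned* genes a +1 log-unit
shift (σ = 0.2), with 100 background genes so that 24 expression bins
always contain control genes — the default was raised from 30 after the
smaller world made bins consisting entirely of set genes possible, which is
a structural failure of the score, not a noisy outcome.

What the generator does **not** emulate — and therefore what a green test
does not establish: splice-aware alignment (reads are ungapped; junction
lifting is out of scope), realistic quality-by-cycle error profiles,
indels, strand-specific protocols, overdispersed biological replicates
(unless enabled), doublets or ambient RNA. The cascade's behaviour on those
inputs is untested by design.

# Numerical choices and degenerate inputs

* Editing level with $n_\mathrm{edit}+n_\mathrm{ref}=0$ is missing (NA),
  never 0; all-missing matrix rows are an error naming the site.
* k-means restarts that produce an empty cluster are retried; duplicated
  initial centres are jittered by 1e-9.
* The exact rank-sum p-value is
  $P(|W - E W| \ge |w_\mathrm{obs} - E W|)$ under the permutation null;
  the normal path subtracts a 0.5 continuity correction and applies the
  standard tie correction to the variance.
* TSV outputs print doubles via `%.17g`, so tables round-trip losslessly
  and identical configs give byte-identical outputs (tested end to end).
* Seeds: every entry point derives per-purpose sub-seeds from the single
  config seed (kept below 2^31); generator functions force their arguments
  before seeding so lazily evaluated inputs cannot perturb the stream.
* The β-convergence check of the generator (coverage 2000, tolerance 0.02)
  is asserted in aggregate — ≥ 95% of site×stage cells within 0.02 and mean
  absolute deviation ≤ 0.02 — because 0.02 is only ~1.9 binomial standard
  deviations per cell at mid-range β, and an every-cell assertion would
  fail a third of seeds by chance.

# Known limitations

Single-contig simulation (multi-chromosome inputs work in the callers, but
the generator emits one contig); no hyper-editing cluster detection; no
C-to-U or other edit types; no statistical genotyping behind the SNP filter
(position/allele matching only); module-score bins follow published
defaults (24 bins, 100 controls) rather than any fitted choice; the CLI
runs the workflow sequentially on one core.
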