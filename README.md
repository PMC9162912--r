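# editscape

Genome-wide A-to-I RNA editing analysis from aligned RNA-seq reads, for
transcriptomics researchers studying how editing changes across development —
bulk time courses and barcoded single-cell data alike.

ADAR enzymes deaminate adenosine (A) to inosine (I) in double-stranded RNA;
sequencers read inosine as guanosine, so editing shows up as A→G mismatches
against the genome. `editscape` implements the standard analysis around that
signal:

- **Site calling.** A pileup filter cascade turns per-sample mismatch counts
  into high-confidence editing sites: base quality ≥ 25 and mapping quality
  ≥ 20, quality-passing coverage *N* ≥ 15, mismatch rate *m* = n_G/N ≥ 0.02, a
  third-allele guard (≤ 1% of reads on neither A nor G), removal of known SNPs
  (A>G / T>C from a supplied VCF), and recurrence in strictly more than 50% of
  samples. Genomic T→C positions are called as minus-strand A-to-I sites.
- **Quantification.** Per-site editing level β = G/(G+A) (other-base reads
  excluded from the denominator); per-sample overall editing level
  Σ n_G / Σ N over high-confidence sites.
- **Annotation.** Genomic region with fixed precedence
  (CDS > 3'UTR > 5'UTR > ncRNA > intron > intergenic), protein recoding via
  the standard codon table across CDS junctions and strands (e.g. the
  glutamate-receptor Q/R, I/V, Y/C changes), repeat-element context
  (SINE/B1 vs other), and a ±5 bp sequence-composition matrix.
- **Temporal patterns.** Seeded k-means (k = 3) over the sites × stages level
  matrix yields `high`/`medium`/`low` co-editing patterns ordered by centroid
  mean, with an SSE elbow curve; ordinary least squares relates overall
  editing to ADAR1/ADAR2 expression with Benjamini–Hochberg correction.
- **Pseudobulk single cell.** Reads are split by cell barcode into cell
  types; editing is quantified per type at the bulk high-confidence
  background sites (level = edited reads / all mapped reads there), and gene
  sets are scored per cell with an expression-bin-matched control score.
- **Synthetic data.** A fully seeded generator produces a reference genome
  with gene/repeat annotation, planted sites following three temporal
  trajectories, heterozygous SNP confounders, bulk and barcoded SAM files,
  and serialized ground truth — the whole pipeline is testable end to end.

## Worked example

Run the whole workflow on a small synthetic study (six genes, twelve planted
sites, eight stages E14.5–P21, three cell types):

```r
library(editscape)
cfg <- read_pipeline_config(overrides = list(
  out_dir = "demo", seed = 42, genome_length = 30000L, n_genes = 6L,
  n_sites_high = 4L, n_sites_medium = 4L, n_sites_low = 4L,
  n_snps = 4L, n_background = 20L, mean_coverage = 40,
  cells_per_type = 5L, celltype_coverage = 30))
cmd_run_all(cfg)
```

```
[editscape] attrition: candidate_sample_calls=181, snp_excluded_sample_calls=32, high_confidence_sites=11
[editscape] barcode split conservation: 1100 grouped + 0 unassigned = 1100 reads
```

181 per-sample candidate calls survive the quality/coverage/mismatch filters;
32 are heterozygous-SNP mimics (β ≈ 0.5) removed by the VCF filter; 11 sites
recur in > 50% of stages. The annotated table:

```r
head(read_site_table("demo/analysis/annotated_sites.tsv")[,
  c("chrom","pos","strand","region","recoding_label","repeat_subfamily",
    "pattern","mean_level")], 5)
```

```
  chrom   pos strand     region recoding_label repeat_subfamily pattern mean_level
1  chrS  3359      +       utr3           <NA>             <NA>     low 0.04758325
2  chrS  7921      - exonic_cds            I/V             <NA>    high 0.40878136
3  chrS  8879      + intergenic           <NA>               B1  medium 0.21067048
4  chrS 13922      +       utr3           <NA>             <NA>  medium 0.24604470
5  chrS 15844      -       utr3           <NA>             <NA>     low 0.12147304
```

Site `chrS:7921` is a minus-strand recoding site (genomic T→C, coding-strand
A→G turning Ile into Val) whose editing rises across development — the planted
analogue of the recoding events in ionotropic glutamate receptors. Overall
editing tracks ADAR expression:

```r
read_site_table("demo/analysis/adar_regression.tsv")
```

```
   gene      slope  intercept pearson_r      p_value flagged      q_value
1 Adar1 0.02658135 -0.1310485 0.9770395 2.974227e-05   FALSE 2.974227e-05
2 Adar2 0.01920283 -0.2250096 0.9838280 1.044598e-05   FALSE 2.089196e-05
```

and the cell type owning the recoding sites detects the most background
sites in the barcoded data:

```r
read_site_table("demo/pseudobulk/site_ratio.tsv")
```

```
  cell_type n_detected      ratio
1   bipolar          5 0.45454545
2  ganglion          2 0.18181818
3       rod          1 0.09090909
```

The same workflow is available from the shell via the bundled launcher:

```sh
Rscript inst/cli/editscape run-all --config my.cfg
Rscript inst/cli/editscape call --min-coverage 20 --out-dir demo
```

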