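# Barcode-split pseudobulk editing: partition barcoded reads by cell type,
# quantify editing at bulk high-confidence "background" sites per type,
# summarize per-type detection ratios, and score gene sets per cell with a
# binned-control module score.

#' Split barcoded reads by cell type
#'
#' Every barcoded read lands in exactly one cell-type group or the
#' unassigned bin; reads without a barcode are unassigned. Read counts are
#' conserved: sum of group counts plus unassigned equals the number of
#' barcoded input reads.
#'
#' @param reads Read table from [parse_alignments()] with a `barcode`
#'   column.
#' @param barcode_map `data.frame` with columns `barcode`, `cell_type`
#'   (barcodes must be unique).
#' @return List with `groups` (named list of read tables), `counts`
#'   (`data.frame` cell_type, read_count), `unassigned` (read table).
#' @export
split_by_celltype <- function(reads, barcode_map) {
  if (anyDuplicated(barcode_map$barcode)) {
    dup <- barcode_map$barcode[duplicated(barcode_map$barcode)][1L]
    stopf("barcode %s mapped to more than one cell type", dup)
  }
  type <- barcode_map$cell_type[match(reads$barcode, barcode_map$barcode)]
  types <- unique(barcode_map$cell_type)
  groups <- lapply(types, function(tp) {
    out <- reads[!is.na(type) & type == tp, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(groups) <- types
  unassigned <- reads[is.na(type), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(groups = groups,
       counts = data.frame(cell_type = types,
                           read_count = vapply(groups, nrow, 0L),
                           stringsAsFactors = FALSE),
       unassigned = unassigned)
}

#' Pseudobulk editing levels at background sites
#'
#' Pileup restricted to the supplied background (bulk high-confidence)
#' positions with the same quality filters as bulk calling. The editing
#' level here is the number of edited-base reads divided by all
#' quality-passing reads mapped to the site — deliberately not the bulk
#' G/(G+A) statistic.
#'
#' @param reads Read table for one cell-type group.
#' @param background Site `data.frame` with `chrom`, `pos`, `strand`.
#' @param genome Reference `DNAStringSet`.
#' @param config A [filter_config()].
#' @return `data.frame`: `chrom`, `pos`, `strand`, `coverage`, `n_edit`,
#'   `level`; sites without coverage in the group are absent.
#' @export
pseudobulk_editing <- function(reads, background, genome,
                               config = filter_config()) {
  if (nrow(background) == 0L) stopf("pseudobulk_editing: empty background")
  counts <- pileup_counts(reads, genome, config)
  idx <- match(paste(background$chrom, background$pos),
               paste(counts$chrom, counts$pos))
  present <- !is.na(idx)
  if (!any(present)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), coverage = integer(),
                      n_edit = integer(), level = numeric(),
                      stringsAsFactors = FALSE))
  }
  cc <- counts[idx[present]]
  plus <- background$strand[present] == "+"
  n_edit <- ifelse(plus, cc$G, cc$C)
  N <- cc$A + cc$C + cc$G + cc$T
  keep <- N >= 1L
  data.frame(chrom = background$chrom[present][keep],
             pos = background$pos[present][keep],
             strand = background$strand[present][keep],
             coverage = N[keep], n_edit = n_edit[keep],
             level = n_edit[keep] / N[keep],
             stringsAsFactors = FALSE)
}

#' Fraction of background sites detected per cell type
#'
#' A site counts as detected in a cell type iff its pseudobulk coverage and
#' edited-read count reach the thresholds; the ratio is detected sites over
#' the full background size.
#'
#' @param evidence_by_type Named list of [pseudobulk_editing()] outputs.
#' @param background Background site `data.frame`.
#' @param min_cov Minimum coverage (default 5).
#' @param min_edit Minimum edited reads (default 2).
#' @return `data.frame`: `cell_type`, `n_detected`, `ratio`.
#' @export
site_ratio <- function(evidence_by_type, background, min_cov = 5L,
                       min_edit = 2L) {
  if (nrow(background) == 0L) stopf("site_ratio: empty background")
  stopifnot(min_cov >= 0, min_edit >= 0)
  rows <- lapply(names(evidence_by_type), function(tp) {
    ev <- evidence_by_type[[tp]]
    det <- sum(ev$coverage >= min_cov & ev$n_edit >= min_edit)
    data.frame(cell_type = tp, n_detected = det,
               ratio = det / nrow(background), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-set module score per cell
#'
#' Expression-bin-matched control scoring in the style of single-cell
#' gene-set enrichment: genes are ranked by mean expression across cells
#' and cut into `n_bins` equal-frequency bins; for each set gene, `n_ctrl`
#' control genes are sampled from its bin (with replacement when the bin is
#' smaller, set genes excluded from the control pool); the score of a cell
#' is its mean expression over set genes minus its mean over the pooled
#' control draws.
#'
#' @param mat Cells x genes numeric matrix on log scale (dimnames
#'   required).
#' @param gene_set Character vector of set genes (all must be in `mat`).
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Controls sampled per set gene (default 100).
#' @param seed Integer seed (scores are deterministic under it).
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(mat, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  if (length(gene_set) == 0L) stopf("module_score: empty gene set")
  genes <- colnames(mat)
  miss <- setdiff(gene_set, genes)
  if (length(miss)) stopf("gene %s absent from expression matrix", miss[1L])
  if (length(genes) < n_bins)
    stopf("module_score: %d genes < n_bins = %d", length(genes), n_bins)
  set.seed(seed)
  avg <- colMeans(mat)
  bin <- ceiling(n_bins * rank(avg, ties.method = "first") / length(avg))
  ctrl <- character(0)
  for (g in gene_set) {
    pool <- genes[bin == bin[[match(g, genes)]]]
    pool <- setdiff(pool, gene_set)
    if (length(pool) == 0L)
      stopf("module_score: no control genes available in the bin of %s", g)
    ctrl <- c(ctrl, sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
  }
  set_mean <- rowMeans(mat[, gene_set, drop = FALSE])
  ctrl_mean <- rowMeans(mat[, ctrl, drop = FALSE])
  set_mean - ctrl_mean
}

#' Run the pseudobulk workflow end to end
#'
#' Splits a barcoded read table, quantifies editing per cell type at the
#' background sites, and summarizes detection ratios.
#'
#' @param reads Barcoded read table from [parse_alignments()].
#' @param barcode_map Barcode-to-cell-type `data.frame`.
#' @param background Bulk high-confidence site `data.frame`.
#' @param genome Reference `DNAStringSet`.
#' @param config A [filter_config()].
#' @param min_cov,min_edit Detection thresholds for [site_ratio()].
#' @return List with `split` ([split_by_celltype()] output), `evidence`
#'   (named list per type) and `ratios`.
#' @export
pseudobulk_pipeline <- function(reads, barcode_map, background, genome,
                                config = filter_config(), min_cov = 5L,
                                min_edit = 2L) {
  sp <- split_by_celltype(reads, barcode_map)
  evidence <- lapply(sp$groups, pseudobulk_editing, background = background,
                     genome = genome, config = config)
  list(split = sp, evidence = evidence,
       ratios = site_ratio(evidence, background, min_cov, min_edit))
}
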