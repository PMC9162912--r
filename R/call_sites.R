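# The high-confidence A-to-I calling cascade: quality-filtered pileup,
# per-sample candidate selection (coverage, mismatch rate, third-allele
# guard), known-SNP exclusion, cross-sample recurrence, and the editing
# statistics built on the surviving sites.

#' Filter thresholds for the calling cascade
#'
#' Defaults are the published cascade: base quality >= 25, mapping quality
#' >= 20, coverage >= 15, A-to-G mismatch rate >= 0.02, and recurrence in
#' strictly more than 50% of samples. The third-allele guard (reads carrying
#' neither the reference nor the edited base capped at 1% of coverage) is
#' this package's explicit version of the noise rejection the published
#' pipeline delegated to its source method. All `>=` thresholds are
#' inclusive, as printed.
#'
#' @param min_base_quality Minimum Phred base quality (inclusive).
#' @param min_mapq Minimum mapping quality (inclusive).
#' @param min_coverage Minimum quality-passing coverage N (inclusive).
#' @param min_mismatch_rate Minimum mismatch rate m = n_edit / N (inclusive).
#' @param recurrence_fraction Site must be a surviving candidate in strictly
#'   more than this fraction of samples.
#' @param max_third_allele_fraction Maximum n_other / N.
#' @param both_strands If `TRUE` (default) genomic T-to-C positions are
#'   called as minus-strand A-to-I sites; `FALSE` restricts to plus-strand
#'   A-to-G, reproducing an unstranded-agnostic literal reading.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 25L, min_mapq = 20L,
                          min_coverage = 15L, min_mismatch_rate = 0.02,
                          recurrence_fraction = 0.5,
                          max_third_allele_fraction = 0.01,
                          both_strands = TRUE) {
  stopifnot(min_base_quality >= 0, min_mapq >= 0, min_coverage >= 0,
            min_mismatch_rate >= 0, max_third_allele_fraction >= 0,
            recurrence_fraction > 0, recurrence_fraction < 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Quality-filtered per-position base counts
#'
#' Piles up reads, wholly excluding reads below the mapping-quality floor
#' and individual bases below the base-quality floor; `N` bases are ignored.
#'
#' @param reads Read table from [parse_alignments()].
#' @param genome Reference `DNAStringSet` (chromosome names must cover the
#'   reads').
#' @param config A [filter_config()].
#' @return `data.table` with columns `chrom`, `pos` (1-based), `A`, `C`,
#'   `G`, `T` counts and `ref` (reference base).
#' @export
pileup_counts <- function(reads, genome, config = filter_config()) {
  missing_chrom <- setdiff(unique(reads$chrom), names(genome))
  if (length(missing_chrom))
    stopf("chromosome %s absent from reference", missing_chrom[1L])
  bases <- read_bases(reads[reads$mapq >= config$min_mapq, , drop = FALSE])
  bases <- bases[bases$qual >= config$min_base_quality & bases$base != "N"]
  if (nrow(bases) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), ref = character()))
  }
  counts <- data.table::dcast(
    bases[, .N, by = .(chrom, pos, base)],
    chrom + pos ~ base, value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T"))
    if (is.null(counts[[b]])) counts[, (b) := 0L]
  data.table::setcolorder(counts, c("chrom", "pos", "A", "C", "G", "T"))
  data.table::setorder(counts, chrom, pos)
  counts[, ref := genome_bases_at(genome, chrom, pos)]
  counts[]
}

#' Per-sample candidate editing sites
#'
#' A position is a candidate iff it shows A-to-G mismatches on the plus
#' strand (reference A, G reads present) or T-to-C on the minus strand
#' (reference T, C reads; counts complemented, reported as strand `-`),
#' with quality-passing coverage `N >= min_coverage`, mismatch rate
#' `m = n_edit/N >= min_mismatch_rate`, and third-allele fraction
#' `n_other/N <= max_third_allele_fraction`.
#'
#' @param counts Output of [pileup_counts()].
#' @param config A [filter_config()].
#' @return `data.frame` of candidates: `chrom`, `pos`, `strand`, `n_ref`,
#'   `n_edit`, `n_other`, `coverage`, `mismatch_rate`, `beta`, `status`.
#' @export
candidate_sites <- function(counts, config = filter_config()) {
  if (nrow(counts) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_ref = integer(),
                      n_edit = integer(), n_other = integer(),
                      coverage = integer(), mismatch_rate = numeric(),
                      beta = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  N <- counts$A + counts$C + counts$G + counts$T
  plus <- counts$ref == "A" & counts$G > 0L
  minus <- config$both_strands & counts$ref == "T" & counts$C > 0L
  build <- function(sel, strand) {
    if (!any(sel)) return(NULL)
    cc <- counts[sel]
    if (strand == "+") {
      n_ref <- cc$A; n_edit <- cc$G; n_other <- cc$C + cc$T
    } else {
      n_ref <- cc$T; n_edit <- cc$C; n_other <- cc$A + cc$G
    }
    data.frame(chrom = cc$chrom, pos = cc$pos, strand = strand,
               n_ref = n_ref, n_edit = n_edit, n_other = n_other,
               coverage = N[sel],
               mismatch_rate = n_edit / N[sel],
               beta = editing_level(n_edit, n_ref),
               status = "candidate", stringsAsFactors = FALSE)
  }
  out <- rbind(build(plus, "+"), build(minus, "-"))
  if (is.null(out)) {
    return(candidate_sites(counts[0L], config))
  }
  keep <- out$coverage >= config$min_coverage &
    out$mismatch_rate >= config$min_mismatch_rate &
    out$n_other / out$coverage <= config$max_third_allele_fraction
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mark candidates matching known SNPs
#'
#' A site is excluded iff a SNP exists at the same chrom/pos whose ref/alt
#' equals the site's mismatch in its strand representation: A>G for
#' plus-strand sites, T>C for minus-strand sites. Excluded sites are kept
#' with `status = "snp_excluded"` for reporting.
#'
#' @param sites Candidate `data.frame` from [candidate_sites()].
#' @param snps SNP `data.frame` from [parse_snps()] (or `NULL`).
#' @return `sites` with updated `status`.
#' @export
exclude_snps <- function(sites, snps) {
  if (is.null(snps) || nrow(snps) == 0L || nrow(sites) == 0L) return(sites)
  site_key <- paste(sites$chrom, sites$pos,
                    ifelse(sites$strand == "+", "A>G", "T>C"))
  snp_key <- paste(snps$chrom, snps$pos, paste0(snps$ref, ">", snps$alt))
  hit <- site_key %in% snp_key
  sites$status[hit] <- "snp_excluded"
  sites
}

#' Cross-sample recurrence filter
#'
#' A site becomes high-confidence iff it is a surviving candidate (all
#' per-sample filters passed, not SNP-excluded) in strictly more than
#' `recurrence_fraction` of all samples. The merged record carries evidence
#' from every sample with coverage >= 1 at the site, candidate or not;
#' samples without coverage are missing.
#'
#' @param per_sample Named list (one element per sample) of candidate
#'   `data.frame`s after [exclude_snps()].
#' @param per_sample_counts Named list of the matching [pileup_counts()]
#'   tables, used to collect evidence at non-candidate samples.
#' @param config A [filter_config()].
#' @return List with `sites` (high-confidence `data.frame`: chrom, pos,
#'   strand, n_samples_candidate, status) and `evidence` (long
#'   `data.frame`: site key columns, sample, n_ref, n_edit, n_other,
#'   coverage, beta).
#' @export
recurrence_filter <- function(per_sample, per_sample_counts,
                              config = filter_config()) {
  n_samples <- length(per_sample)
  if (n_samples == 0L) stopf("recurrence_filter: zero samples")
  if (is.null(names(per_sample)))
    names(per_sample) <- paste0("sample", seq_len(n_samples))
  cand <- rbindlist(lapply(names(per_sample), function(s) {
    df <- per_sample[[s]]
    if (nrow(df) == 0L) return(NULL)
    data.table(chrom = df$chrom, pos = df$pos, strand = df$strand,
               status = df$status, sample = s)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   strand = character(),
                                   n_samples_candidate = integer(),
                                   status = character()),
                evidence = data.frame()))
  }
  tally <- cand[status == "candidate",
                .(n_samples_candidate = .N), by = .(chrom, pos, strand)]
  keep <- tally[n_samples_candidate > config$recurrence_fraction * n_samples]
  data.table::setorder(keep, chrom, pos)
  sites <- as.data.frame(keep)
  sites$status <- rep("high_confidence", nrow(sites))
  evidence <- site_evidence(sites, per_sample_counts)
  list(sites = sites, evidence = evidence)
}

# Collect per-sample strand-aware counts at given sites from pileup tables.
#' @noRd
site_evidence <- function(sites, per_sample_counts) {
  if (nrow(sites) == 0L) return(data.frame())
  rows <- lapply(names(per_sample_counts), function(s) {
    counts <- per_sample_counts[[s]]
    idx <- match(paste(sites$chrom, sites$pos),
                 paste(counts$chrom, counts$pos))
    present <- !is.na(idx)
    if (!any(present)) return(NULL)
    cc <- counts[idx[present]]
    plus <- sites$strand[present] == "+"
    n_ref <- ifelse(plus, cc$A, cc$T)
    n_edit <- ifelse(plus, cc$G, cc$C)
    n_other <- ifelse(plus, cc$C + cc$T, cc$A + cc$G)
    N <- cc$A + cc$C + cc$G + cc$T
    keep <- N >= 1L
    data.frame(chrom = sites$chrom[present][keep],
               pos = sites$pos[present][keep],
               strand = sites$strand[present][keep],
               sample = s,
               n_ref = n_ref[keep], n_edit = n_edit[keep],
               n_other = n_other[keep], coverage = N[keep],
               beta = editing_level(n_edit[keep], n_ref[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Per-site editing level G/(G+A)
#'
#' The editing level is the fraction of edited-base reads among reads
#' supporting either the reference or the edited base; other-base reads are
#' excluded from the denominator. Undefined (NA) when `n_edit + n_ref = 0`.
#'
#' @param n_edit,n_ref Integer vectors of edited- and reference-supporting
#'   read counts.
#' @return Numeric vector of levels in [0,1], NA where undefined.
#' @export
editing_level <- function(n_edit, n_ref) {
  denom <- n_edit + n_ref
  ifelse(denom > 0, n_edit / denom, NA_real_)
}

#' Overall editing level of a sample
#'
#' The ratio of total edited-base reads to total quality-passing mapped
#' reads, summed over all high-confidence sites with evidence in the
#' sample.
#'
#' @param evidence Long evidence `data.frame` from [recurrence_filter()].
#' @param sample Sample name.
#' @return A scalar in [0,1], or NA if the sample has no evidence.
#' @export
overall_editing_level <- function(evidence, sample) {
  ev <- evidence[evidence$sample == sample, , drop = FALSE]
  if (nrow(ev) == 0L) return(NA_real_)
  sum(ev$n_edit) / sum(ev$coverage)
}

#' Build the sites-by-stages editing matrix
#'
#' @param evidence Long evidence `data.frame` from [recurrence_filter()].
#' @param stages Ordered sample/stage names (matrix column order).
#' @return Object of class `editing_matrix`: list with `levels` (numeric
#'   matrix, NA = missing), `missing` (logical mask), `sites` (site key
#'   `data.frame`) and `stages`.
#' @export
build_matrix <- function(evidence, stages) {
  if (nrow(evidence) == 0L) {
    m <- matrix(numeric(), 0L, length(stages),
                dimnames = list(NULL, stages))
    return(structure(list(levels = m, missing = m == m,
                          sites = data.frame(chrom = character(),
                                             pos = integer(),
                                             strand = character()),
                          stages = stages), class = "editing_matrix"))
  }
  key <- unique(evidence[, c("chrom", "pos", "strand")])
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  rownames(key) <- NULL
  m <- matrix(NA_real_, nrow(key), length(stages),
              dimnames = list(paste(key$chrom, key$pos, key$strand, sep = ":"),
                              stages))
  ri <- match(paste(evidence$chrom, evidence$pos, evidence$strand),
              paste(key$chrom, key$pos, key$strand))
  ci <- match(evidence$sample, stages)
  ok <- !is.na(ci)
  m[cbind(ri[ok], ci[ok])] <- evidence$beta[ok]
  structure(list(levels = m, missing = is.na(m), sites = key,
                 stages = stages), class = "editing_matrix")
}

#' Run the full calling cascade over a set of samples
#'
#' Convenience driver: parse each SAM, optionally deduplicate, pile up,
#' select per-sample candidates, exclude known SNPs, and apply the
#' recurrence filter. Logs per-filter attrition counts.
#'
#' @param sam_files Named character vector of SAM paths (names = sample /
#'   stage ids, in stage order).
#' @param genome Reference `DNAStringSet` (or FASTA path).
#' @param snps SNP `data.frame`, VCF path, or `NULL`.
#' @param config A [filter_config()].
#' @param dedup Collapse clonal reads before pileup (default `TRUE`).
#' @return Object of class `editing_call`: list with `sites`, `evidence`,
#'   `per_sample` (candidate tables), `attrition` (`data.frame`) and
#'   `stages`.
#' @export
call_editing_sites <- function(sam_files, genome, snps = NULL,
                               config = filter_config(), dedup = TRUE) {
  if (is.character(genome)) genome <- load_genome(genome)
  if (is.character(snps)) snps <- parse_snps(snps)
  if (is.null(names(sam_files)))
    names(sam_files) <- paste0("sample", seq_along(sam_files))
  per_sample <- list(); per_counts <- list()
  for (s in names(sam_files)) {
    reads <- parse_alignments(sam_files[[s]], dedup = dedup)
    counts <- pileup_counts(reads, genome, config)
    cand <- candidate_sites(counts, config)
    per_sample[[s]] <- exclude_snps(cand, snps)
    per_counts[[s]] <- counts
  }
  rec <- recurrence_filter(per_sample, per_counts, config)
  n_cand <- sum(vapply(per_sample, function(df)
    sum(df$status == "candidate"), 0L))
  n_excl <- sum(vapply(per_sample, function(df)
    sum(df$status == "snp_excluded"), 0L))
  attrition <- data.frame(
    step = c("candidate_sample_calls", "snp_excluded_sample_calls",
             "high_confidence_sites"),
    count = c(n_cand, n_excl, nrow(rec$sites)))
  structure(list(sites = rec$sites, evidence = rec$evidence,
                 per_sample = per_sample, attrition = attrition,
                 stages = names(sam_files)),
            class = "editing_call")
}
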