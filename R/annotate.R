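# Site annotation: genomic region with a fixed precedence order, protein
# recoding consequence via the standard codon table, repeat-element overlap,
# flanking sequence composition, and editing-level comparison across repeat
# classes.

# Standard genetic code (NCBI table 1), written out explicitly so that the
# package's translation is independent of Biostrings::GENETIC_CODE (which
# tests use as an oracle).
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' @noRd
translate_codon <- function(codon) {
  aa <- CODON_TABLE[codon]
  if (anyNA(aa)) stopf("invalid codon: %s", codon[is.na(aa)][1L])
  unname(aa)
}

#' @noRd
revcomp_chr <- function(s) {
  vapply(s, function(x)
    as.character(reverseComplement(DNAString(x))), "", USE.NAMES = FALSE)
}

# Map every CDS genomic position of a codable gene to its coding-sequence
# index. Returns list(coding_seq = character scalar on the coding strand,
# genomic_pos = integer vector parallel to the coding sequence).
#' @noRd
coding_map <- function(model, genome) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$codable) stopf("gene %s is not codable", model$gene_id)
  cds <- model$cds
  ord <- if (model$strand == "-") order(-cds$start) else order(cds$start)
  pos <- unlist(lapply(ord, function(j) {
    p <- seq.int(cds$start[j], cds$end[j])
    if (model$strand == "-") rev(p) else p
  }), use.names = FALSE)
  chrom_seq <- genome[[model$chrom]]
  bases <- strsplit(as.character(chrom_seq), "")[[1L]][pos]
  if (model$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  list(coding_seq = paste0(bases, collapse = ""), genomic_pos = pos)
}

#' Classify the protein-level consequence of an A-to-G edit
#'
#' Reconstructs the coding-strand codon containing the site (across CDS
#' junctions, honouring the annotated frame), applies the A-to-G change on
#' the coding strand (for minus-strand genes the genomic T-to-C site is
#' reverse-complemented), translates both codons with the standard genetic
#' code, and labels the change `"X/Y"` in one-letter amino-acid code.
#'
#' @param chrom,pos Site coordinate (1-based).
#' @param model A `gene_model` from [parse_gene_models()] whose CDS contains
#'   the site.
#' @param genome Reference `DNAStringSet`.
#' @return A list with `kind` (`"synonymous"`, `"nonsynonymous"` or
#'   `"not_coding"`), `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `label`.
#' @export
classify_recoding <- function(chrom, pos, model, genome) {
  not_coding <- list(kind = "not_coding", codon_ref = NA_character_,
                     codon_alt = NA_character_, aa_ref = NA_character_,
                     aa_alt = NA_character_, label = NA_character_)
  if (!inherits(model, "gene_model") || !model$codable) return(not_coding)
  if (!identical(model$chrom, chrom)) return(not_coding)
  cm <- coding_map(model, genome)
  idx <- match(pos, cm$genomic_pos)
  if (is.na(idx)) return(not_coding)
  # frame consistency: the annotated frame of the first transcribed CDS
  # chunk must be 0 for the codon grid below to hold
  first <- if (model$strand == "-") which.max(model$cds$end) else which.min(model$cds$start)
  if (model$cds$frame[first] != 0L) {
    warnf("gene %s: first CDS frame is %d, expected 0; site %s:%d left not_coding",
          model$gene_id, model$cds$frame[first], chrom, pos)
    return(not_coding)
  }
  base <- substr(cm$coding_seq, idx, idx)
  if (base != "A") {
    warnf("site %s:%d is %s (not A) on the coding strand of %s",
          chrom, pos, base, model$gene_id)
    return(not_coding)
  }
  codon_i <- (idx - 1L) %/% 3L
  off <- idx - codon_i * 3L           # 1..3 within the codon
  codon_ref <- substr(cm$coding_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_alt <- codon_ref
  substr(codon_alt, off, off) <- "G"
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  list(kind = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
       codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt,
       label = paste0(aa_ref, "/", aa_alt))
}

REGION_CATEGORIES <- c("exonic_cds", "utr3", "utr5", "ncRNA", "intronic",
                       "intergenic")

# Build one GRanges per region category from a gene-model list.
#' @noRd
region_index <- function(models) {
  grab <- function(getter, coding_only = NA) {
    rows <- lapply(models, function(m) {
      if (!is.na(coding_only) && (nrow(m$cds) > 0L) != coding_only) return(NULL)
      df <- getter(m)
      if (is.null(df) || nrow(df) == 0L) return(NULL)
      data.frame(chrom = m$chrom, start = df$start, end = df$end,
                 gene_id = m$gene_id, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      return(GRanges())
    }
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
  }
  list(
    exonic_cds = grab(function(m) m$cds),
    utr3 = grab(function(m) m$utr3),
    utr5 = grab(function(m) m$utr5),
    ncRNA = grab(function(m) m$exons, coding_only = FALSE),
    span = grab(function(m) {
      iv <- rbind(m$exons, m$cds[, c("start", "end"), drop = FALSE],
                  m$utr5, m$utr3)
      if (nrow(iv) == 0L) return(NULL)
      data.frame(start = min(iv$start), end = max(iv$end))
    }))
}

#' Assign each site a genomic region
#'
#' Precedence when a site overlaps several annotations:
#' `exonic_cds > utr3 > utr5 > ncRNA > intronic > intergenic`. Ties within a
#' category are broken by lexicographic `gene_id`.
#'
#' @param sites `data.frame` with `chrom`, `pos` (1-based).
#' @param models Gene-model list from [parse_gene_models()].
#' @return `data.frame` with columns `region` and `gene_id` (NA when
#'   intergenic), one row per input site.
#' @export
assign_region <- function(sites, models) {
  n <- nrow(sites)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(region = character(), gene_id = character()))
  idx <- region_index(models)
  q <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  claim <- function(gr, cat) {
    if (length(gr) == 0L) return()
    hits <- findOverlaps(q, gr)
    if (length(hits) == 0L) return()
    hit_gene <- S4Vectors::mcols(gr)$gene_id[subjectHits(hits)]
    o <- order(queryHits(hits), hit_gene)   # lexicographic gene tie-break
    qh <- queryHits(hits)[o]
    first <- !duplicated(qh)
    sel <- qh[first][region[qh[first]] == "intergenic"]
    gid <- hit_gene[o][first][region[qh[first]] == "intergenic"]
    region[sel] <<- cat
    gene_id[sel] <<- gid
  }
  claim(idx$exonic_cds, "exonic_cds")
  claim(idx$utr3, "utr3")
  claim(idx$utr5, "utr5")
  claim(idx$ncRNA, "ncRNA")
  claim(idx$span, "intronic")
  data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Overlap sites with a repeat annotation
#'
#' When a site falls inside nested repeats the innermost (shortest) interval
#' wins, approximating "most specific element".
#'
#' @param sites `data.frame` with `chrom`, `pos`.
#' @param repeats `GRanges` from [read_repeats()].
#' @return `data.frame` with `repeat_family`, `repeat_subfamily` (NA for
#'   non-repeat sites).
#' @export
overlap_repeats <- function(sites, repeats) {
  n <- nrow(sites)
  fam <- rep(NA_character_, n)
  sub <- rep(NA_character_, n)
  if (n > 0L && length(repeats) > 0L) {
    q <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
    hits <- findOverlaps(q, repeats)
    if (length(hits)) {
      w <- GenomicRanges::width(repeats)[subjectHits(hits)]
      o <- order(queryHits(hits), w)
      qh <- queryHits(hits)[o]; sh <- subjectHits(hits)[o]
      first <- !duplicated(qh)
      fam[qh[first]] <- S4Vectors::mcols(repeats)$family[sh[first]]
      sub[qh[first]] <- S4Vectors::mcols(repeats)$subfamily[sh[first]]
    }
  }
  data.frame(repeat_family = fam, repeat_subfamily = sub,
             stringsAsFactors = FALSE)
}

#' Flanking sequence composition around editing sites
#'
#' Takes the 11-mer centred on each site from the edited strand (minus-strand
#' sites are reverse-complemented, so position 0 is always A) and tabulates
#' per-position base counts and frequencies for positions -5..+5. Sites
#' closer than 5 bp to a contig end are skipped and counted.
#'
#' @param sites `data.frame` with `chrom`, `pos`, `strand`.
#' @param genome Reference `DNAStringSet`.
#' @param flank Half-window size (default 5).
#' @return A list with `counts` and `freq` (4 x (2*flank+1) matrices, rows
#'   A/C/G/T, columns -flank..flank), `n_sites` used and `n_skipped`.
#' @export
context_matrix <- function(sites, genome, flank = 5L) {
  positions <- seq.int(-flank, flank)
  counts <- matrix(0L, nrow = 4, ncol = length(positions),
                   dimnames = list(c("A", "C", "G", "T"), positions))
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    if (!ch %in% names(genome)) stopf("chromosome %s absent from reference", ch)
    L <- length(genome[[ch]])
    p <- sites$pos[i]
    if (p - flank < 1L || p + flank > L) { n_skipped <- n_skipped + 1L; next }
    s <- as.character(subseq(genome[[ch]], p - flank, p + flank))
    if (identical(sites$strand[i], "-")) s <- revcomp_chr(s)
    b <- strsplit(s, "")[[1L]]
    ri <- match(b, rownames(counts))
    ok <- !is.na(ri)
    ij <- cbind(ri[ok], seq_along(b)[ok])
    counts[ij] <- counts[ij] + 1L
    n_used <- n_used + 1L
  }
  freq <- if (n_used > 0L) sweep(counts, 2L, colSums(counts), "/") else counts
  list(counts = counts, freq = freq, n_sites = n_used, n_skipped = n_skipped)
}

# Exact null distribution of the rank-sum W (sum of ranks of group 1) when
# ranks are untied: dynamic programming over the number of ways to choose
# n1 of the ranks 1..N with a given sum.
#' @noRd
ranksum_exact_dist <- function(n1, n2) {
  N <- n1 + n2
  smax <- sum(seq.int(N - n1 + 1L, N))
  smin <- sum(seq_len(n1))
  # ways[k+1, s+1] = number of subsets of size k with rank-sum s
  ways <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (j in seq_len(N)) {
    for (k in rev(seq_len(min(j, n1)))) {
      srange <- seq.int(j, smax)
      ways[k + 1L, srange + 1L] <- ways[k + 1L, srange + 1L] +
        ways[k, srange - j + 1L]
    }
  }
  p <- ways[n1 + 1L, ]
  support <- which(p > 0) - 1L
  list(w = support, prob = p[support + 1L] / choose(N, n1))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation null (dynamic programming over untied ranks) when both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction. The two-sided p-value is the null probability of a rank-sum
#' at least as far from its expectation as observed.
#'
#' @param x,y Numeric vectors (group 1 = `x`).
#' @param exact_max Largest group size for the exact null (default 12).
#' @return List with `W` (rank-sum of `x`), `U` (Mann-Whitney U), `p_value`
#'   and `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("rank_sum_test: empty group")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  EW <- n1 * (n1 + n2 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    dist <- ranksum_exact_dist(n1, n2)
    p <- sum(dist$prob[abs(dist$w - EW) >= abs(W - EW) - 1e-9])
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (abs(W - EW) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(z, lower.tail = FALSE)
    p <- min(1, max(0, p))
    method <- "normal"
  }
  list(W = W, U = U, p_value = p, method = method)
}

#' Compare editing levels across repeat classes
#'
#' Splits annotated sites into B1, other-repeat and non-repeat classes by
#' their mean editing level across stages and runs two-sided rank-sum tests
#' for B1 vs other-repeat and B1 vs non-repeat.
#'
#' @param sites Annotated site `data.frame` with columns `repeat_family`,
#'   `repeat_subfamily` and `mean_level`.
#' @return A list with `levels` (named list of per-class level vectors) and
#'   `tests` (`data.frame` of comparisons; skipped ones flagged).
#' @export
compare_levels_by_repeat <- function(sites) {
  is_rep <- !is.na(sites$repeat_family)
  is_b1 <- is_rep & !is.na(sites$repeat_subfamily) & sites$repeat_subfamily == "B1"
  lv <- list(
    B1 = sites$mean_level[is_b1],
    other_repeat = sites$mean_level[is_rep & !is_b1],
    non_repeat = sites$mean_level[!is_rep])
  one <- function(a, b) {
    if (length(lv[[a]]) == 0L || length(lv[[b]]) == 0L) {
      return(data.frame(comparison = paste0(a, "_vs_", b), n1 = length(lv[[a]]),
                        n2 = length(lv[[b]]), W = NA_real_, p_value = NA_real_,
                        method = "skipped_empty_class",
                        stringsAsFactors = FALSE))
    }
    t <- rank_sum_test(lv[[a]], lv[[b]])
    data.frame(comparison = paste0(a, "_vs_", b), n1 = length(lv[[a]]),
               n2 = length(lv[[b]]), W = t$W, p_value = t$p_value,
               method = t$method, stringsAsFactors = FALSE)
  }
  list(levels = lv,
       tests = rbind(one("B1", "other_repeat"), one("B1", "non_repeat")))
}

#' Annotate high-confidence sites
#'
#' Convenience driver adding region, recoding, repeat and mean-level columns
#' to a site table.
#'
#' @param sites Site `data.frame` with `chrom`, `pos`, `strand`.
#' @param models Gene-model list (or `NULL` to skip region/recoding).
#' @param repeats Repeat `GRanges` (or `NULL` to skip).
#' @param genome Reference `DNAStringSet`.
#' @param matrix Optional [build_matrix()] result used for `mean_level`.
#' @return The site table with columns `region`, `gene_id`, `recoding`,
#'   `recoding_label`, `repeat_family`, `repeat_subfamily`, `mean_level`.
#' @export
annotate_sites <- function(sites, models = NULL, repeats = NULL, genome,
                           matrix = NULL) {
  out <- as.data.frame(sites)
  if (!is.null(models)) {
    reg <- assign_region(out, models)
    out$region <- reg$region
    out$gene_id <- reg$gene_id
    out$recoding <- "not_coding"
    out$recoding_label <- NA_character_
    cds_i <- which(out$region == "exonic_cds")
    for (i in cds_i) {
      rc <- classify_recoding(out$chrom[i], out$pos[i],
                              models[[out$gene_id[i]]], genome)
      out$recoding[i] <- rc$kind
      out$recoding_label[i] <- rc$label
    }
  } else {
    out$region <- NA_character_; out$gene_id <- NA_character_
    out$recoding <- NA_character_; out$recoding_label <- NA_character_
  }
  if (!is.null(repeats)) {
    rp <- overlap_repeats(out, repeats)
    out$repeat_family <- rp$repeat_family
    out$repeat_subfamily <- rp$repeat_subfamily
  } else {
    out$repeat_family <- NA_character_; out$repeat_subfamily <- NA_character_
  }
  if (!is.null(matrix)) {
    key <- paste(out$chrom, out$pos, out$strand)
    mkey <- paste(matrix$sites$chrom, matrix$sites$pos, matrix$sites$strand)
    out$mean_level <- rowMeans(matrix$levels, na.rm = TRUE)[match(key, mkey)]
  }
  out
}
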