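# Synthetic-study generator: reference genome with gene and repeat
# annotation, planted A-to-I editing sites following stage-dependent
# trajectories, heterozygous A/G SNP confounders, bulk and cell-barcoded
# reads with a configurable error model, ADAR expression tables, and a
# serialized ground truth driving every end-to-end test.

# Fixed gene geometry (bp): [UTR5][CDS1][intron][CDS2][UTR3] in transcript
# order; CDS1+CDS2 = 900, divisible by 3, split so the second chunk starts
# at a non-zero frame.
UTR5_LEN <- 150L; CDS1_LEN <- 451L; INTRON_LEN <- 200L
CDS2_LEN <- 449L; UTR3_LEN <- 600L
GENE_LEN <- UTR5_LEN + CDS1_LEN + INTRON_LEN + CDS2_LEN + UTR3_LEN

DEFAULT_STAGES <- c("E14.5", "E17.5", "P0", "P3", "P7", "P10", "P14", "P21")

#' Simulation configuration
#'
#' Collects every knob of the synthetic study. Defaults describe the stated
#' world the test-suite runs in: 8 ordered developmental stages, 60 planted
#' sites split over three temporal trajectories, 20 heterozygous A/G SNP
#' confounders, mean site coverage 50 and per-base error rate 0.001.
#'
#' @param seed Integer seed (mandatory); all randomness derives from it.
#' @param genome_length Reference length in bp (single contig).
#' @param n_genes Number of non-overlapping protein-coding genes.
#' @param read_length Simulated read length.
#' @param mean_coverage Mean (Poisson) read depth per planted position.
#' @param n_sites Named vector: planted sites per trajectory
#'   (`high`, `medium`, `low`).
#' @param n_snps Heterozygous A/G SNPs planted away from editing sites.
#' @param n_background Unedited A positions given coverage, so that false
#'   calls have somewhere to happen.
#' @param epsilon Per-base sequencing error rate in [0, 0.05].
#' @param qual_high,qual_low,low_qual_frac Phred quality mixture.
#' @param mapq,low_mapq,low_mapq_frac Mapping-quality mixture (contaminant
#'   fraction gets `low_mapq`).
#' @param min_spacing Minimum distance between planted positions, kept above
#'   twice the read length so one read never spans two targets.
#' @param stages Ordered stage names.
#' @param frac_cds,frac_utr3,frac_b1,frac_other_repeat Compartment fractions
#'   of the planted sites (remainder is intergenic non-repeat).
#' @param cell_types Cell-type names for the barcoded corpus.
#' @param cells_per_type Barcodes emitted per cell type.
#' @param celltype_coverage Mean per-site coverage within one cell type.
#' @param expr_slope,expr_intercept,expr_sigma ADAR FPKM model: FPKM =
#'   slope * (mean planted level at stage) + intercept + N(0, sigma).
#' @param n_background_genes Uncorrelated genes in the expression tables.
#' @param cell_expr_delta,cell_expr_sigma Log-expression shift for genes in
#'   the owning cell type and cell-level noise of the single-cell matrix.
#' @param overdispersion Optional negative-binomial size parameter; `NULL`
#'   keeps the Poisson coverage model.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 120000L,
                       n_genes = 12L,
                       read_length = 100L,
                       mean_coverage = 50,
                       n_sites = c(high = 20L, medium = 20L, low = 20L),
                       n_snps = 20L,
                       n_background = 150L,
                       epsilon = 0.001,
                       qual_high = 37L, qual_low = 20L, low_qual_frac = 0.05,
                       mapq = 60L, low_mapq = 10L, low_mapq_frac = 0.05,
                       min_spacing = 250L,
                       stages = DEFAULT_STAGES,
                       frac_cds = 0.2, frac_utr3 = 0.4, frac_b1 = 0.25,
                       frac_other_repeat = 0.05,
                       cell_types = c("bipolar", "ganglion", "rod"),
                       cells_per_type = 20L,
                       celltype_coverage = 30,
                       expr_slope = 40, expr_intercept = 5, expr_sigma = 1,
                       n_background_genes = 100L,
                       cell_expr_delta = 1, cell_expr_sigma = 0.2,
                       overdispersion = NULL) {
  if (missing(seed) || is.null(seed)) stopf("sim_config: seed is mandatory")
  if (epsilon < 0 || epsilon > 0.05) stopf("epsilon must lie in [0, 0.05]")
  stopifnot(genome_length >= 10000, n_genes >= 0, read_length > 0,
            mean_coverage >= 0, all(n_sites >= 0), n_snps >= 0,
            n_background >= 0, length(stages) >= 1)
  if (!all(c("high", "medium", "low") %in% names(n_sites)))
    stopf("n_sites must be named high/medium/low")
  structure(as.list(environment()), class = "sim_config")
}

# ---- reference ------------------------------------------------------------

#' @noRd
make_gene_model <- function(gene_start, strand, id, name, chrom) {
  g0 <- gene_start
  if (strand == "+") {
    utr5 <- c(g0, g0 + UTR5_LEN - 1L)
    cds1 <- c(utr5[2L] + 1L, utr5[2L] + CDS1_LEN)
    intr <- c(cds1[2L] + 1L, cds1[2L] + INTRON_LEN)
    cds2 <- c(intr[2L] + 1L, intr[2L] + CDS2_LEN)
    utr3 <- c(cds2[2L] + 1L, cds2[2L] + UTR3_LEN)
    exons <- data.frame(start = c(utr5[1L], cds2[1L]),
                        end = c(cds1[2L], utr3[2L]))
    cds <- data.frame(start = c(cds1[1L], cds2[1L]),
                      end = c(cds1[2L], cds2[2L]),
                      frame = c(0L, (3L - CDS1_LEN %% 3L) %% 3L))
  } else {
    utr3 <- c(g0, g0 + UTR3_LEN - 1L)
    cds2 <- c(utr3[2L] + 1L, utr3[2L] + CDS2_LEN)
    intr <- c(cds2[2L] + 1L, cds2[2L] + INTRON_LEN)
    cds1 <- c(intr[2L] + 1L, intr[2L] + CDS1_LEN)
    utr5 <- c(cds1[2L] + 1L, cds1[2L] + UTR5_LEN)
    exons <- data.frame(start = c(utr3[1L], cds1[1L]),
                        end = c(cds2[2L], utr5[2L]))
    cds <- data.frame(start = c(cds2[1L], cds1[1L]),
                      end = c(cds2[2L], cds1[2L]),
                      frame = c((3L - CDS1_LEN %% 3L) %% 3L, 0L))
  }
  structure(list(gene_id = id, gene_name = name, chrom = chrom,
                 strand = strand,
                 exons = exons, cds = cds,
                 utr5 = data.frame(start = utr5[1L], end = utr5[2L]),
                 utr3 = data.frame(start = utr3[1L], end = utr3[2L]),
                 codable = TRUE),
            class = "gene_model")
}

REPEAT_SIZES <- c(B1 = 135L, B2 = 190L, B4 = 250L, L1 = 500L,
                  MTA = 350L, SR = 60L)
REPEAT_FAMILY_OF <- c(B1 = "SINE", B2 = "SINE", B4 = "SINE", L1 = "LINE",
                      MTA = "LTR", SR = "Simple_repeat")

#' Simulate a reference genome with gene and repeat annotation
#'
#' Draws a uniform-composition genome, lays out non-overlapping two-exon
#' protein-coding genes on alternating strands, and places repeat intervals
#' (SINE/B1, B2, B4, LINE, LTR, simple repeats) in intergenic gaps plus a B1
#' inside every third gene's 3'UTR. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `models` (gene-model list)
#'   and `repeats` (`data.frame`: chrom, start, end, name, strand, family,
#'   subfamily, placement).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  L <- as.integer(config$genome_length)
  chrom <- "chrS"
  genome_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  genome <- DNAStringSet(paste0(genome_chars, collapse = ""))
  names(genome) <- chrom

  models <- list()
  gene_bounds <- matrix(integer(), ncol = 2)
  if (config$n_genes > 0L) {
    slot <- L %/% config$n_genes
    if (slot < GENE_LEN + 800L)
      stopf("requested features exceed genome capacity: %d genes of %d bp need > %d bp",
            config$n_genes, GENE_LEN, config$n_genes * (GENE_LEN + 800L))
    for (i in seq_len(config$n_genes)) {
      off <- sample(200:(slot - GENE_LEN - 600L), 1L)
      g0 <- (i - 1L) * slot + off
      strand <- if (i %% 2L == 1L) "+" else "-"
      id <- sprintf("gene%02d", i)
      models[[id]] <- make_gene_model(g0, strand, id, sprintf("Gene%02d", i),
                                      chrom)
      gene_bounds <- rbind(gene_bounds, c(g0, g0 + GENE_LEN - 1L))
    }
  }

  # repeats: intergenic gaps get two B1 plus one other-family interval
  reps <- list()
  other_cycle <- c("B2", "B4", "L1", "MTA", "SR")
  gaps <- if (nrow(gene_bounds)) {
    cbind(c(1L, gene_bounds[, 2L] + 50L),
          c(gene_bounds[, 1L] - 50L, L))
  } else cbind(1L, L)
  oi <- 0L
  for (g in seq_len(nrow(gaps))) {
    lo <- gaps[g, 1L]; hi <- gaps[g, 2L]
    if (hi - lo < 1500L) next
    cur <- lo + sample(20:120, 1L)
    for (b in 1:2) {
      if (cur + REPEAT_SIZES[["B1"]] > hi) break
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = chrom, start = cur, end = cur + REPEAT_SIZES[["B1"]] - 1L,
        name = sprintf("B1_g%d_%d", g, b), strand = "+",
        family = "SINE", subfamily = "B1", placement = "intergenic",
        stringsAsFactors = FALSE)
      cur <- cur + REPEAT_SIZES[["B1"]] + as.integer(config$min_spacing) + 60L
    }
    oi <- oi + 1L
    sub <- other_cycle[(oi - 1L) %% length(other_cycle) + 1L]
    sz <- REPEAT_SIZES[[sub]]
    if (cur + sz <= hi) {
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = chrom, start = cur, end = cur + sz - 1L,
        name = sprintf("%s_g%d", sub, g), strand = "+",
        family = REPEAT_FAMILY_OF[[sub]],
        subfamily = if (sub == "SR") "(A)n" else sub,
        placement = "intergenic", stringsAsFactors = FALSE)
    }
  }
  # one B1 inside every third gene's 3'UTR
  gi <- 0L
  for (m in models) {
    gi <- gi + 1L
    if (gi %% 3L != 0L) next
    u <- m$utr3
    st <- u$start[1L] + 100L
    reps[[length(reps) + 1L]] <- data.frame(
      chrom = chrom, start = st, end = st + REPEAT_SIZES[["B1"]] - 1L,
      name = sprintf("B1_utr_%s", m$gene_id), strand = m$strand,
      family = "SINE", subfamily = "B1", placement = "utr",
      stringsAsFactors = FALSE)
  }
  repeats <- if (length(reps)) do.call(rbind, reps) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), strand = character(), family = character(),
               subfamily = character(), placement = character())
  list(genome = genome, models = models, repeats = repeats, chrom = chrom)
}

#' Write gene models as a GTF subset
#'
#' Emits `exon`, `CDS`, `five_prime_utr` and `three_prime_utr` rows with
#' `gene_id`/`gene_name` attributes; CDS rows carry their frame.
#'
#' @param models Gene-model list.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  lines <- character()
  fmt <- function(m, type, df, frame = NULL) {
    if (nrow(df) == 0L) return(character())
    sprintf("%s\teditscape\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; gene_name \"%s\";",
            m$chrom, type, df$start, df$end, m$strand,
            if (is.null(frame)) "." else as.character(frame),
            m$gene_id, m$gene_name)
  }
  for (m in models) {
    lines <- c(lines,
               fmt(m, "exon", m$exons),
               sprintf("%s\teditscape\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; gene_name \"%s\";",
                       m$chrom, m$cds$start, m$cds$end, m$strand, m$cds$frame,
                       m$gene_id, m$gene_name),
               fmt(m, "five_prime_utr", m$utr5),
               fmt(m, "three_prime_utr", m$utr3))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- site planting --------------------------------------------------------

# Trajectory generators. Stage axis x in [0,1]; `high`/`medium` follow a
# normalized logistic (monotone, exact start/end), `low` is constant with
# small jitter. See the methods vignette for the invariants each satisfies.
#' @noRd
make_trajectory <- function(pattern, n_stages) {
  x <- seq(0, 1, length.out = n_stages)
  if (pattern == "low") {
    base <- runif(1, 0.02, 0.10)
    return(pmin(pmax(base + runif(n_stages, -0.02, 0.02), 0), 1))
  }
  if (pattern == "high") {
    a <- runif(1, 0.05, 0.15); f <- runif(1, 0.55, 0.90)
  } else {
    a <- runif(1, 0.03, 0.10); f <- runif(1, 0.22, 0.45)
  }
  s <- stats::plogis(10 * (x - 0.45))
  a + (f - a) * (s - s[1L]) / (s[n_stages] - s[1L])
}

#' @noRd
greedy_pick <- function(candidates, n, accepted_pos, min_spacing, what) {
  # candidates: data.frame with a pos column, pre-shuffled
  picked <- integer()
  for (i in seq_len(nrow(candidates))) {
    if (length(picked) == n) break
    p <- candidates$pos[i]
    if (length(accepted_pos) && min(abs(accepted_pos - p)) < min_spacing) next
    picked <- c(picked, i)
    accepted_pos <- c(accepted_pos, p)
  }
  if (length(picked) < n)
    stopf("not enough A positions in compartment %s: needed %d, found %d",
          what, n, length(picked))
  list(rows = candidates[picked, , drop = FALSE], accepted = accepted_pos)
}

#' Plant editing sites, SNP confounders and background positions
#'
#' Places sites with reference base A on their strand across genomic
#' compartments (nonsynonymous CDS positions, 3'UTRs, intergenic B1
#' elements, other repeats, intergenic non-repeat), assigns each a temporal
#' trajectory (`high`/`medium`/`low`), plants heterozygous A/G SNPs away
#' from sites, reserves unedited background positions, and assigns each site
#' an owning cell type (the first cell type owns every nonsynonymous site).
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return An object of class `sim_truth`; see the vignette for its layout.
#' @export
plant_sites <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  force(reference)   # evaluate before seeding: the generator seeds itself
  set.seed(derive_seed(config$seed, 2L))
  chrom <- reference$chrom
  L <- length(reference$genome[[chrom]])
  genome_chars <- strsplit(as.character(reference$genome[[chrom]]), "")[[1L]]
  total <- sum(config$n_sites)
  n_cds <- round(config$frac_cds * total)
  n_b1 <- round(config$frac_b1 * total)
  n_orep <- round(config$frac_other_repeat * total)
  n_utr3 <- round(config$frac_utr3 * total)
  n_inter <- total - n_cds - n_b1 - n_orep - n_utr3
  if (n_inter < 0L) stopf("compartment fractions exceed 1")
  spacing <- as.integer(config$min_spacing)
  if (spacing < 2L * config$read_length)
    warnf("min_spacing %d < 2*read_length; reads may span two planted targets",
          spacing)
  accepted <- integer()

  in_any <- function(pos, bounds) {
    if (nrow(bounds) == 0L) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(bounds)))
      out <- out | (pos >= bounds[r, 1L] & pos <= bounds[r, 2L])
    out
  }
  gene_bounds <- do.call(rbind, lapply(reference$models, function(m)
    c(min(m$exons$start), max(m$exons$end))))
  if (is.null(gene_bounds)) gene_bounds <- matrix(integer(), ncol = 2)
  rep_bounds <- as.matrix(reference$repeats[, c("start", "end"), drop = FALSE])

  # CDS compartment: coding-strand A whose A->G edit is nonsynonymous
  cds_cand <- list()
  for (m in reference$models) {
    if (!m$codable) next
    cm <- coding_map(m, reference$genome)
    bases <- strsplit(cm$coding_seq, "")[[1L]]
    for (idx in which(bases == "A")) {
      codon_i <- (idx - 1L) %/% 3L
      off <- idx - codon_i * 3L
      codon <- substr(cm$coding_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      alt <- codon; substr(alt, off, off) <- "G"
      if (CODON_TABLE[[codon]] == CODON_TABLE[[alt]]) next
      cds_cand[[length(cds_cand) + 1L]] <- data.frame(
        pos = cm$genomic_pos[idx], strand = m$strand, gene_id = m$gene_id,
        recoding_label = paste0(CODON_TABLE[[codon]], "/", CODON_TABLE[[alt]]),
        stringsAsFactors = FALSE)
    }
  }
  cds_cand <- if (length(cds_cand)) do.call(rbind, cds_cand) else
    data.frame(pos = integer(), strand = character(), gene_id = character(),
               recoding_label = character())
  cds_cand <- cds_cand[sample.int(nrow(cds_cand)), , drop = FALSE]
  pick <- greedy_pick(cds_cand, n_cds, accepted, spacing, "CDS")
  accepted <- pick$accepted
  cds_sites <- pick$rows

  compartment_pick <- function(pos, strand, n, what, gene_id = NA_character_) {
    df <- data.frame(pos = pos, strand = strand, gene_id = gene_id,
                     recoding_label = NA_character_, stringsAsFactors = FALSE)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    pick <- greedy_pick(df, n, accepted, spacing, what)
    accepted <<- pick$accepted
    pick$rows
  }

  # intergenic B1 elements: plus-strand A positions
  b1_iv <- reference$repeats[reference$repeats$subfamily == "B1" &
                               reference$repeats$placement == "intergenic", ,
                             drop = FALSE]
  b1_pos <- unlist(lapply(seq_len(nrow(b1_iv)), function(r)
    seq.int(b1_iv$start[r], b1_iv$end[r])), use.names = FALSE)
  b1_pos <- b1_pos[genome_chars[b1_pos] == "A"]
  b1_sites <- compartment_pick(b1_pos, "+", n_b1, "B1")

  # other repeats (non-B1)
  or_iv <- reference$repeats[reference$repeats$subfamily != "B1", , drop = FALSE]
  or_pos <- unlist(lapply(seq_len(nrow(or_iv)), function(r)
    seq.int(or_iv$start[r], or_iv$end[r])), use.names = FALSE)
  or_pos <- or_pos[genome_chars[or_pos] == "A"]
  orep_sites <- compartment_pick(or_pos, "+", n_orep, "other_repeat")

  # 3'UTR (sense-strand A, repeat-free so compartments stay crisp)
  utr_cand <- list()
  for (m in reference$models) {
    u <- m$utr3
    p <- seq.int(u$start[1L], u$end[1L])
    want <- if (m$strand == "+") "A" else "T"
    p <- p[genome_chars[p] == want & !in_any(p, rep_bounds)]
    if (length(p))
      utr_cand[[length(utr_cand) + 1L]] <- data.frame(
        pos = p, strand = m$strand, gene_id = m$gene_id,
        stringsAsFactors = FALSE)
  }
  utr_cand <- do.call(rbind, utr_cand)
  utr3_sites <- compartment_pick(utr_cand$pos, utr_cand$strand, n_utr3, "3'UTR",
                                 gene_id = utr_cand$gene_id)

  # intergenic non-repeat
  inter_pos <- setdiff(which(genome_chars == "A"), accepted)
  inter_pos <- inter_pos[inter_pos > 10L & inter_pos < L - 10L]
  inter_pos <- inter_pos[!in_any(inter_pos, gene_bounds) &
                           !in_any(inter_pos, rep_bounds)]
  inter_sites <- compartment_pick(inter_pos, "+", n_inter, "intergenic")

  tag <- function(df, what) { df$compartment <- rep(what, nrow(df)); df }
  sites <- rbind(
    tag(cds_sites, "cds"),
    tag(b1_sites, "b1"),
    tag(orep_sites, "other_repeat"),
    tag(utr3_sites, "utr3"),
    tag(inter_sites, "intergenic"))
  sites$chrom <- chrom
  n_stages <- length(config$stages)
  # trajectory assignment in compartment order: CDS sites (the recoding
  # story) all land in the high pattern by design
  pattern <- rep(c("high", "medium", "low"),
                 times = c(config$n_sites[["high"]], config$n_sites[["medium"]],
                           config$n_sites[["low"]]))
  if (length(pattern) != nrow(sites)) stopf("internal: pattern/site mismatch")
  sites$pattern <- pattern
  betas <- t(vapply(pattern, make_trajectory, numeric(n_stages),
                    n_stages = n_stages))
  colnames(betas) <- config$stages
  rownames(betas) <- NULL

  # owner cell types: first type owns the CDS (nonsynonymous) block and is
  # strictly the largest owner so ranking tests have a unique answer
  types <- config$cell_types
  owner <- rep(NA_character_, nrow(sites))
  if (length(types) >= 1L) {
    n1 <- max(ceiling(0.4 * nrow(sites)), sum(sites$compartment == "cds"))
    owner[seq_len(n1)] <- types[1L]
    rest <- which(is.na(owner))
    if (length(types) > 1L) {
      owner[rest] <- rep(types[-1L], length.out = length(rest))
    } else owner[rest] <- types[1L]
  }
  sites$owner <- owner
  sites$nonsyn <- !is.na(sites$recoding_label)

  # SNP confounders and unedited background positions (plus-strand A)
  free_a <- which(genome_chars == "A")
  free_a <- free_a[free_a > 10L & free_a < L - 10L]
  snp_rows <- compartment_pick(free_a, "+", config$n_snps, "SNP")
  bg_rows <- compartment_pick(free_a, "+", config$n_background, "background")
  snps <- data.frame(chrom = rep(chrom, nrow(snp_rows)), pos = snp_rows$pos,
                     ref = rep("A", nrow(snp_rows)),
                     alt = rep("G", nrow(snp_rows)), stringsAsFactors = FALSE)
  background <- data.frame(chrom = rep(chrom, nrow(bg_rows)),
                           pos = bg_rows$pos, stringsAsFactors = FALSE)

  # cell barcodes
  n_cells <- length(types) * config$cells_per_type
  barcodes <- character(0)
  if (n_cells > 0L) {
    repeat {
      barcodes <- vapply(seq_len(n_cells), function(i)
        paste0(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
               collapse = ""), "")
      if (!anyDuplicated(barcodes)) break
    }
  }
  barcode_map <- data.frame(
    barcode = barcodes,
    cell_type = rep(types, each = config$cells_per_type),
    stringsAsFactors = FALSE)

  sites <- sites[, c("chrom", "pos", "strand", "pattern", "compartment",
                     "gene_id", "recoding_label", "nonsyn", "owner")]
  rownames(sites) <- NULL
  structure(list(sites = sites, betas = betas, snps = snps,
                 background = background, stages = config$stages,
                 cell_types = types, barcode_map = barcode_map,
                 reference = reference, config = config),
            class = "sim_truth")
}

# ---- read simulation ------------------------------------------------------

# Vectorized in-place single-character replacement.
#' @noRd
str_set_at <- function(s, at, value) {
  substring(s, at, at) <- value
  s
}

# Generate one block of ungapped reads over a target table using the current
# RNG state. targets: data.frame(pos, edit_base, p). Returns a data.frame of
# SAM-ready reads.
#' @noRd
sim_read_block <- function(genome_str, L, targets, coverage, config, prefix) {
  rl <- as.integer(config$read_length)
  nT <- nrow(targets)
  n <- if (is.null(config$overdispersion)) rpois(nT, coverage) else
    rnbinom(nT, size = config$overdispersion, mu = coverage)
  total <- sum(n)
  if (total == 0L) {
    return(data.frame(qname = character(), pos = integer(), mapq = integer(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  t_idx <- rep.int(seq_len(nT), n)
  pos <- targets$pos[t_idx]
  start <- pos - sample.int(rl, total, replace = TRUE) + 1L
  start <- pmin(pmax(start, 1L), L - rl + 1L)
  seqs <- substring(genome_str, start, start + rl - 1L)
  edited <- runif(total) < targets$p[t_idx]
  k <- pos - start + 1L
  if (any(edited))
    seqs[edited] <- str_set_at(seqs[edited], k[edited],
                               targets$edit_base[t_idx][edited])
  # sequencing errors: uniform replacement with another base
  if (config$epsilon > 0) {
    n_err <- rbinom(total, rl, config$epsilon)
    for (i in which(n_err > 0L)) {
      at <- sample.int(rl, n_err[i])
      for (a in at) {
        cur <- substring(seqs[i], a, a)
        substring(seqs[i], a, a) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }
  qv <- sample(c(config$qual_high, config$qual_low), total * rl,
               replace = TRUE,
               prob = c(1 - config$low_qual_frac, config$low_qual_frac))
  qlong <- intToUtf8(qv + 33L)
  ends <- seq_len(total) * rl
  quals <- substring(qlong, ends - rl + 1L, ends)
  mapq <- ifelse(runif(total) < config$low_mapq_frac,
                 config$low_mapq, config$mapq)
  data.frame(qname = sprintf("%s_%06d", prefix, seq_len(total)),
             pos = start, mapq = as.integer(mapq), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' @noRd
write_sam <- function(reads, chrom, L, path, barcode = NULL,
                      barcode_tag = "CB") {
  rl <- nchar(reads$seq)
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, chrom, reads$pos, reads$mapq, rl,
                  reads$seq, reads$qual)
  if (!is.null(barcode))
    body <- paste0(body, sprintf("\t%s:Z:%s", barcode_tag, barcode))
  o <- order(reads$pos, reads$qname)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, L)),
             path)
  cat(body[o], file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Simulate bulk reads for one stage
#'
#' Per planted target (editing site, SNP or background position) the read
#' depth is Poisson with the configured mean; each read overlapping an
#' editing site shows the edited base with that site's stage-specific
#' probability, SNP positions show the alternate allele with probability 0.5
#' in every stage, and every base is independently corrupted to a uniformly
#' chosen other base with probability `epsilon`.
#'
#' @param truth A `sim_truth` from [plant_sites()].
#' @param config The matching [sim_config()].
#' @param stage Stage name (must be one of `truth$stages`).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(truth, config, stage, path) {
  force(truth)
  si <- match(stage, truth$stages)
  if (is.na(si)) stopf("unknown stage: %s", stage)
  set.seed(derive_seed(config$seed, 10L + si))
  chrom <- truth$reference$chrom
  genome_str <- as.character(truth$reference$genome[[chrom]])
  L <- nchar(genome_str)
  targets <- rbind(
    data.frame(pos = truth$sites$pos,
               edit_base = ifelse(truth$sites$strand == "+", "G", "C"),
               p = truth$betas[, si], stringsAsFactors = FALSE),
    data.frame(pos = truth$snps$pos, edit_base = truth$snps$alt,
               p = rep(0.5, nrow(truth$snps)), stringsAsFactors = FALSE),
    data.frame(pos = truth$background$pos,
               edit_base = rep("G", nrow(truth$background)),
               p = rep(0, nrow(truth$background)), stringsAsFactors = FALSE))
  reads <- sim_read_block(genome_str, L, targets, config$mean_coverage,
                          config, prefix = paste0(stage, "_r"))
  write_sam(reads, chrom, L, path)
}

#' Simulate barcoded single-cell reads for one stage
#'
#' Each cell type covers every planted site, but shows editing only at the
#' sites it owns (elsewhere the editing probability is 0). Reads carry a
#' cell barcode in the configured SAM tag, drawn uniformly from the owning
#' type's barcode pool.
#'
#' @inheritParams simulate_reads
#' @param barcode_tag SAM tag to write barcodes into (default `"CB"`).
#' @return The barcode map `data.frame` (barcode, cell_type), invisibly.
#' @export
simulate_barcoded_reads <- function(truth, config, stage, path,
                                    barcode_tag = "CB") {
  si <- match(stage, truth$stages)
  if (is.na(si)) stopf("unknown stage: %s", stage)
  chrom <- truth$reference$chrom
  genome_str <- as.character(truth$reference$genome[[chrom]])
  L <- nchar(genome_str)
  blocks <- list(); bcs <- list()
  for (ti in seq_along(truth$cell_types)) {
    type <- truth$cell_types[ti]
    set.seed(derive_seed(config$seed, 100L + si * 10L + ti))
    p <- ifelse(truth$sites$owner == type, truth$betas[, si], 0)
    targets <- data.frame(
      pos = truth$sites$pos,
      edit_base = ifelse(truth$sites$strand == "+", "G", "C"),
      p = p, stringsAsFactors = FALSE)
    blk <- sim_read_block(genome_str, L, targets, config$celltype_coverage,
                          config, prefix = sprintf("%s_%s", stage, type))
    pool <- truth$barcode_map$barcode[truth$barcode_map$cell_type == type]
    blocks[[ti]] <- blk
    bcs[[ti]] <- sample(pool, nrow(blk), replace = TRUE)
  }
  reads <- do.call(rbind, blocks)
  write_sam(reads, chrom, L, path,
            barcode = unlist(bcs, use.names = FALSE),
            barcode_tag = barcode_tag)
  invisible(truth$barcode_map)
}

# ---- expression -----------------------------------------------------------

#' Simulate per-stage ADAR and background gene expression
#'
#' Adar1/Adar2 FPKM follow an affine function of the mean planted editing
#' level at each stage plus Gaussian noise; background genes are
#' uncorrelated with the editing axis.
#'
#' @inheritParams simulate_reads
#' @return `data.frame`: `gene` column plus one FPKM column per stage.
#' @export
simulate_expression <- function(truth, config) {
  force(truth)
  set.seed(derive_seed(config$seed, 3L))
  mb <- colMeans(truth$betas)
  S <- length(truth$stages)
  a <- config$expr_slope; b <- config$expr_intercept; s <- config$expr_sigma
  vals <- rbind(a * mb + b + rnorm(S, 0, s),
                1.5 * a * mb + 2 * b + rnorm(S, 0, s))
  for (i in seq_len(config$n_background_genes)) {
    gm <- runif(1, 1, 50)
    vals <- rbind(vals, gm + rnorm(S, 0, gm * 0.1))
  }
  out <- data.frame(gene = c("Adar1", "Adar2",
                             sprintf("bg%03d",
                                     seq_len(config$n_background_genes))),
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("gene", truth$stages)
  rownames(out) <- NULL
  out
}

#' Simulate a log-scale single-cell expression matrix
#'
#' Cells are the barcodes of the truth object; genes are the site-hosting
#' genes plus uncorrelated background genes. Genes hosting sites owned by a
#' cell's type are shifted up by `cell_expr_delta` log units in that type's
#' cells — the signal the gene-set module score is meant to find.
#'
#' @inheritParams simulate_reads
#' @return List with `mat` (cells x genes), `cells` (`data.frame` barcode,
#'   cell_type) and `gene_sets` (named list; `nonsynonymous` = genes hosting
#'   nonsynonymous sites).
#' @export
simulate_cell_expression <- function(truth, config) {
  force(truth)
  set.seed(derive_seed(config$seed, 4L))
  host <- sort(unique(truth$sites$gene_id[!is.na(truth$sites$gene_id)]))
  genes <- c(host, sprintf("bg%03d", seq_len(config$n_background_genes)))
  base <- runif(length(genes), 0.5, 4)
  names(base) <- genes
  cells <- truth$barcode_map
  mat <- matrix(rnorm(nrow(cells) * length(genes), 0, config$cell_expr_sigma),
                nrow = nrow(cells), ncol = length(genes),
                dimnames = list(cells$barcode, genes))
  mat <- sweep(mat, 2L, base, "+")
  owned_genes <- function(type) {
    unique(truth$sites$gene_id[!is.na(truth$sites$gene_id) &
                                 truth$sites$owner == type])
  }
  for (type in truth$cell_types) {
    og <- intersect(owned_genes(type), genes)
    if (length(og))
      mat[cells$cell_type == type, og] <-
        mat[cells$cell_type == type, og] + config$cell_expr_delta
  }
  nonsyn_genes <- sort(unique(truth$sites$gene_id[truth$sites$nonsyn]))
  list(mat = mat, cells = cells,
       gene_sets = list(nonsynonymous = nonsyn_genes))
}

# ---- truth serialization and the full corpus ------------------------------

#' Serialize simulation ground truth to plain text
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- cbind(truth$sites, as.data.frame(truth$betas))
  names(sites)[-(1:ncol(truth$sites))] <- paste0("beta_", truth$stages)
  write_tsv(sites, file.path(dir, "truth_sites.tsv"))
  write_tsv(truth$snps, file.path(dir, "truth_snps.tsv"))
  write_tsv(truth$background, file.path(dir, "truth_background.tsv"))
  write_tsv(truth$barcode_map, file.path(dir, "barcode_map.tsv"))
  jsonlite::write_json(
    list(stages = truth$stages, cell_types = truth$cell_types,
         seed = truth$config$seed),
    file.path(dir, "truth_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read serialized ground truth back
#'
#' Restores the site/beta/SNP/background tables and metadata written by
#' [write_truth()] (not the reference objects, which live in their own
#' standard-format files).
#'
#' @param dir Directory written by [write_truth()].
#' @return A list mirroring the serializable parts of `sim_truth`.
#' @export
read_truth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth_meta.json"),
                              simplifyVector = TRUE)
  sites_full <- read_site_table(file.path(dir, "truth_sites.tsv"))
  beta_cols <- paste0("beta_", meta$stages)
  betas <- as.matrix(sites_full[, beta_cols, drop = FALSE])
  colnames(betas) <- meta$stages
  rownames(betas) <- NULL
  list(sites = sites_full[, setdiff(names(sites_full), beta_cols),
                          drop = FALSE],
       betas = betas,
       snps = read_site_table(file.path(dir, "truth_snps.tsv")),
       background = read_site_table(file.path(dir, "truth_background.tsv")),
       barcode_map = read_site_table(file.path(dir, "barcode_map.tsv")),
       stages = meta$stages, cell_types = meta$cell_types, seed = meta$seed)
}

#' Generate the full synthetic corpus on disk
#'
#' Writes reference FASTA, gene GTF, repeat BED, SNP VCF, one bulk SAM per
#' stage, a barcoded SAM (last stage) with its barcode map, bulk and
#' single-cell expression tables, and the serialized ground truth.
#' Byte-identical for identical configs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The `sim_truth`, invisibly.
#' @export
simulate_corpus <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  truth <- plant_sites(config, reference)
  writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  write_gene_models_gtf(reference$models, file.path(dir, "genes.gtf"))
  write_repeats_bed(reference$repeats, file.path(dir, "repeats.bed"))
  write_snps_vcf(truth$snps, file.path(dir, "snps.vcf"))
  for (stage in config$stages)
    simulate_reads(truth, config, stage,
                   file.path(dir, sprintf("reads_%s.sam", stage)))
  last <- config$stages[length(config$stages)]
  simulate_barcoded_reads(truth, config, last,
                          file.path(dir, "barcoded.sam"))
  expr <- simulate_expression(truth, config)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  ce <- simulate_cell_expression(truth, config)
  ce_df <- data.frame(barcode = rownames(ce$mat),
                      cell_type = ce$cells$cell_type,
                      as.data.frame(ce$mat), check.names = FALSE,
                      stringsAsFactors = FALSE)
  write_tsv(ce_df, file.path(dir, "cell_expression.tsv"))
  jsonlite::write_json(ce$gene_sets, file.path(dir, "gene_sets.json"))
  write_truth(truth, dir)
  invisible(truth)
}
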