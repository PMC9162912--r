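# Fixture builders shared by the test files. Everything is generated in
# code at test time; nothing binary is stored.

qchar <- function(q) intToUtf8(rep(q + 33L, length.out = max(length(q), 1L)))

qstring <- function(quals) intToUtf8(quals + 33L)

sam_header <- function(chrom = "chr1", len = 10000L) {
  c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

sam_line <- function(qname, chrom, pos, seq,
                     qual = strrep(qchar(40L), nchar(seq)),
                     mapq = 60L, flag = 0L,
                     cigar = paste0(nchar(seq), "M"), tags = NULL) {
  line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, flag, chrom, pos, mapq, cigar, seq, qual)
  if (!is.null(tags)) line <- paste(c(line, tags), collapse = "\t")
  line
}

write_sam_fixture <- function(lines, chrom = "chr1", len = 10000L,
                              path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(chrom, len), lines), path)
  path
}

make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(make_genome(seqs), path)
  path
}

# Directly build a gene_model object (same layout parse_gene_models emits).
gene_model_fixture <- function(gene_id, chrom, strand, exons, cds = NULL,
                               utr5 = NULL, utr3 = NULL, codable = !is.null(cds)) {
  empty <- data.frame(start = integer(), end = integer())
  if (is.null(cds)) { cds <- empty; cds$frame <- integer() }
  structure(list(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds,
                 utr5 = utr5 %||% empty, utr3 = utr3 %||% empty,
                 codable = codable),
            class = "gene_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulation config used by the shared corpus and several tests.
small_sim_config <- function(seed = 5, ...) {
  editscape::sim_config(
    seed = seed, genome_length = 30000L, n_genes = 6L,
    n_sites = c(high = 4L, medium = 4L, low = 4L), n_snps = 4L,
    n_background = 20L, mean_coverage = 40, cells_per_type = 5L,
    celltype_coverage = 30, ...)
}

# One shared small end-to-end run per test session (memoized).
.shared <- new.env(parent = emptyenv())

shared_small_run <- function() {
  if (is.null(.shared$run)) {
    out_dir <- file.path(tempdir(), "editscape_shared_run")
    cfg <- editscape::read_pipeline_config(overrides = list(
      out_dir = out_dir, seed = 5, log_level = "quiet",
      genome_length = 30000L, n_genes = 6L,
      n_sites_high = 4L, n_sites_medium = 4L, n_sites_low = 4L,
      n_snps = 4L, n_background = 20L, mean_coverage = 40,
      cells_per_type = 5L, celltype_coverage = 30))
    editscape::cmd_run_all(cfg)
    .shared$run <- list(cfg = cfg, dir = out_dir,
                        truth = editscape::read_truth(file.path(out_dir, "corpus")))
  }
  .shared$run
}

# ---------------------------------------------------------------------------
# Independent brute-force cascade oracle. Parses the SAM text itself
# (ungapped records only), walks every read base with plain loops, applies
# the filter definitions literally, and never touches the package pileup.
naive_cascade <- function(sam_files, genome_chars, snps, min_bq = 25,
                          min_mapq = 20, min_cov = 15, min_m = 0.02,
                          rec_frac = 0.5, max_other = 0.01,
                          both_strands = TRUE) {
  count_sample <- function(path) {
    counts <- list()   # key "pos" -> c(A,C,G,T)
    for (ln in readLines(path)) {
      if (startsWith(ln, "@")) next
      f <- strsplit(ln, "\t")[[1]]
      flag <- as.integer(f[2])
      if (bitwAnd(flag, 4L + 256L + 2048L) != 0L) next
      if (as.integer(f[5]) < min_mapq) next
      pos <- as.integer(f[4])
      stopifnot(grepl("^[0-9]+M$", f[6]))   # oracle handles ungapped only
      seq <- strsplit(f[10], "")[[1]]
      qual <- utf8ToInt(f[11]) - 33L
      for (i in seq_along(seq)) {
        if (qual[i] < min_bq || seq[i] == "N") next
        key <- as.character(pos + i - 1L)
        if (is.null(counts[[key]])) counts[[key]] <- c(A = 0, C = 0, G = 0, T = 0)
        counts[[key]][seq[i]] <- counts[[key]][seq[i]] + 1
      }
    }
    counts
  }
  sample_counts <- lapply(sam_files, count_sample)
  snp_keys <- if (is.null(snps) || nrow(snps) == 0) character() else
    paste(snps$pos, snps$ref, snps$alt)
  per_sample_cand <- lapply(sample_counts, function(counts) {
    out <- character()
    for (key in names(counts)) {
      p <- as.integer(key)
      cnt <- counts[[key]]
      N <- sum(cnt)
      ref <- genome_chars[p]
      reps <- list()
      if (ref == "A" && cnt[["G"]] > 0) reps <- c(reps, list(c("+", "G", "A")))
      if (both_strands && ref == "T" && cnt[["C"]] > 0)
        reps <- c(reps, list(c("-", "C", "T")))
      for (r in reps) {
        n_edit <- cnt[[r[2]]]; n_ref <- cnt[[r[3]]]
        n_other <- N - n_edit - n_ref
        if (N < min_cov) next
        if (n_edit / N < min_m) next
        if (n_other / N > max_other) next
        if (r[1] == "+" && paste(p, "A", "G") %in% snp_keys) next
        if (r[1] == "-" && paste(p, "T", "C") %in% snp_keys) next
        out <- c(out, paste0(p, r[1]))
      }
    }
    out
  })
  all_keys <- unique(unlist(per_sample_cand))
  n_samples <- length(sam_files)
  tallies <- vapply(all_keys, function(k)
    sum(vapply(per_sample_cand, function(x) k %in% x, TRUE)), 0)
  kept <- all_keys[tallies > rec_frac * n_samples]
  # per-sample strand-aware counts at kept sites
  evidence <- list()
  for (s in seq_along(sample_counts)) {
    for (k in kept) {
      p <- as.integer(sub("[+-]$", "", k))
      strand <- sub("^[0-9]+", "", k)
      cnt <- sample_counts[[s]][[as.character(p)]]
      if (is.null(cnt) || sum(cnt) < 1) next
      if (strand == "+") {
        ev <- c(n_ref = cnt[["A"]], n_edit = cnt[["G"]], N = sum(cnt))
      } else {
        ev <- c(n_ref = cnt[["T"]], n_edit = cnt[["C"]], N = sum(cnt))
      }
      evidence[[paste(k, s)]] <- ev
    }
  }
  list(sites = sort(kept), evidence = evidence)
}

# Random mini-corpus for the cascade oracle: short genome, several samples,
# reads of mixed quality/mapq with editing planted at random A/T positions.
random_mini_corpus <- function(seed, n_samples = 3, genome_len = 400,
                               n_reads = 250, read_len = 30) {
  set.seed(seed)
  genome_chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  genome <- make_genome(list(chr1 = paste0(genome_chars, collapse = "")))
  edit_pos <- sample(which(genome_chars %in% c("A", "T")), 12)
  edit_p <- runif(length(edit_pos), 0.05, 0.6)
  snp_pos <- sample(setdiff(which(genome_chars == "A"), edit_pos), 3)
  snps <- data.frame(chrom = "chr1", pos = snp_pos, ref = "A", alt = "G")
  sams <- character(n_samples)
  for (s in seq_len(n_samples)) {
    lines <- character(n_reads)
    for (r in seq_len(n_reads)) {
      st <- sample.int(genome_len - read_len + 1L, 1L)
      seq <- genome_chars[st:(st + read_len - 1L)]
      for (j in seq_along(edit_pos)) {
        k <- edit_pos[j] - st + 1L
        if (k >= 1 && k <= read_len && runif(1) < edit_p[j])
          seq[k] <- if (genome_chars[edit_pos[j]] == "A") "G" else "C"
      }
      for (j in seq_along(snp_pos)) {
        k <- snp_pos[j] - st + 1L
        if (k >= 1 && k <= read_len && runif(1) < 0.5) seq[k] <- "G"
      }
      quals <- sample(c(40L, 20L), read_len, replace = TRUE, prob = c(0.9, 0.1))
      mapq <- sample(c(60L, 10L), 1L, prob = c(0.92, 0.08))
      lines[r] <- sam_line(sprintf("s%d_r%d", s, r), "chr1", st,
                           paste0(seq, collapse = ""),
                           qual = qstring(quals), mapq = mapq)
    }
    sams[s] <- write_sam_fixture(lines, "chr1", genome_len)
  }
  names(sams) <- paste0("sample", seq_len(n_samples))
  list(sams = sams, genome = genome, genome_chars = genome_chars, snps = snps)
}

# ---------------------------------------------------------------------------
# Genome carrying one gene whose CDS is an arbitrary sequence.
coding_fixture <- function(cds_seq, strand = "+") {
  # layout: 1..50 pad, utr5 51..60, CDS 61..(60+n), utr3 ..(+20), pad
  n <- nchar(cds_seq)
  stopifnot(n %% 3 == 0)
  genomic_cds <- if (strand == "+") cds_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  genome <- make_genome(list(chr1 = paste0(
    strrep("C", 50), strrep("T", 10), genomic_cds, strrep("C", 20),
    strrep("T", 30))))
  exons <- data.frame(start = 51L, end = 60L + n + 20L)
  cds <- data.frame(start = 61L, end = 60L + n, frame = 0L)
  model <- gene_model_fixture("g1", "chr1", strand, exons, cds,
                              utr5 = data.frame(start = 51L, end = 60L),
                              utr3 = data.frame(start = 61L + n,
                                                end = 60L + n + 20L))
  list(genome = genome, model = model, cds_start = 61L, cds_len = n)
}

matrix_fixture <- function(levels, stages = paste0("s", seq_len(ncol(levels)))) {
  ev <- do.call(rbind, lapply(seq_len(nrow(levels)), function(i) {
    do.call(rbind, lapply(seq_len(ncol(levels)), function(j) {
      if (is.na(levels[i, j])) return(NULL)
      data.frame(chrom = "chr1", pos = i * 1000L, strand = "+",
                 sample = stages[j], n_ref = 50L, n_edit = 50L, n_other = 0L,
                 coverage = 100L, beta = levels[i, j],
                 stringsAsFactors = FALSE)
    }))
  }))
  build_matrix(ev, stages)
}

# Three trajectories separated by >= 0.2 at every stage, plus binomial
# read-sampling noise at the given coverage.
trajectory_matrix <- function(n_per = 100, coverage = 50, seed = 1,
                              stages = 8) {
  set.seed(seed)
  x <- seq(0, 1, length.out = stages)
  mu <- rbind(high = 0.5 + 0.4 * x, medium = 0.25 + 0.2 * x,
              low = rep(0.05, stages))
  truth <- rep(rownames(mu), each = n_per)
  lv <- do.call(rbind, lapply(truth, function(tr)
    rbinom(stages, coverage, mu[tr, ]) / coverage))
  list(matrix = matrix_fixture(lv), truth = truth, mu = mu)
}
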