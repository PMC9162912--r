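# The calling cascade: pileup quality filters, candidate thresholds, SNP
# exclusion, recurrence, editing statistics, and the brute-force oracle.

test_that("pileup honours base- and mapping-quality floors", {
  genome <- make_genome(list(chr1 = strrep("A", 100)))
  lines <- c(
    sam_line("r1", "chr1", 10, "A", qual = qchar(30)),
    sam_line("r2", "chr1", 10, "A", qual = qchar(30)),
    sam_line("r3", "chr1", 10, "G", qual = qchar(30)),
    sam_line("r4", "chr1", 10, "G", qual = qchar(20)),   # base below q25
    sam_line("r5", "chr1", 10, "G", qual = qchar(30), mapq = 10L),  # low mapq
    sam_line("r6", "chr1", 10, "N", qual = qchar(30)))   # N ignored
  counts <- pileup_counts(parse_alignments(write_sam_fixture(lines)), genome)
  expect_equal(counts$A, 2L)
  expect_equal(counts$G, 1L)
  expect_equal(counts$C + counts$T, 0L)
  # boundary inclusivity: q25 and mapq20 are in
  lines2 <- c(sam_line("r1", "chr1", 5, "G", qual = qchar(25), mapq = 20L),
              sam_line("r2", "chr1", 5, "G", qual = qchar(24), mapq = 20L),
              sam_line("r3", "chr1", 5, "G", qual = qchar(25), mapq = 19L))
  counts2 <- pileup_counts(parse_alignments(write_sam_fixture(lines2)), genome)
  expect_equal(counts2$G, 1L)
  expect_error(
    pileup_counts(parse_alignments(write_sam_fixture(
      sam_line("r", "chrX", 1, "A"))), genome),
    "chrX absent")
})

test_that("candidate thresholds are inclusive exactly as printed", {
  genome <- make_genome(list(chr1 = strrep("A", 50)))
  mk <- function(n_a, n_g, pos = 10) {
    lines <- c(
      if (n_a > 0) sapply(seq_len(n_a), function(i)
        sam_line(paste0("a", i), "chr1", pos, "A")),
      if (n_g > 0) sapply(seq_len(n_g), function(i)
        sam_line(paste0("g", i), "chr1", pos, "G")))
    counts <- pileup_counts(parse_alignments(write_sam_fixture(lines)), genome)
    candidate_sites(counts)
  }
  expect_equal(nrow(mk(98, 2)), 1L)        # m = 0.02 inclusive
  expect_equal(mk(98, 2)$beta, 0.02)
  expect_equal(nrow(mk(981, 19)), 0L)      # m = 0.019 < 0.02
  expect_equal(nrow(mk(980, 20)), 1L)      # m = 0.02
  expect_equal(nrow(mk(9, 5)), 0L)         # N = 14 < 15
  expect_equal(nrow(mk(10, 5)), 1L)        # N = 15
})

test_that("minus-strand T>C sites are complemented and reported as strand -", {
  genome <- make_genome(list(chr1 = strrep("T", 50)))
  lines <- c(sapply(1:40, function(i) sam_line(paste0("t", i), "chr1", 10, "T")),
             sapply(1:10, function(i) sam_line(paste0("c", i), "chr1", 10, "C")))
  counts <- pileup_counts(parse_alignments(write_sam_fixture(lines)), genome)
  cand <- candidate_sites(counts)
  expect_equal(cand$strand, "-")
  expect_equal(cand$n_edit, 10L)
  expect_equal(cand$n_ref, 40L)
  expect_equal(cand$beta, 10 / 50)
  # restricted to plus strand when both_strands = FALSE
  expect_equal(nrow(candidate_sites(counts,
                                    filter_config(both_strands = FALSE))), 0L)
})

test_that("third-allele guard rejects noisy positions", {
  genome <- make_genome(list(chr1 = strrep("A", 50)))
  lines <- c(sapply(1:90, function(i) sam_line(paste0("a", i), "chr1", 10, "A")),
             sapply(1:8, function(i) sam_line(paste0("g", i), "chr1", 10, "G")),
             sapply(1:2, function(i) sam_line(paste0("c", i), "chr1", 10, "C")))
  counts <- pileup_counts(parse_alignments(write_sam_fixture(lines)), genome)
  expect_equal(nrow(candidate_sites(counts)), 0L)   # 2/100 other > 1%
  expect_equal(nrow(candidate_sites(
    counts, filter_config(max_third_allele_fraction = 0.02))), 1L)
})

test_that("exclude_snps matches mismatch identity on either strand", {
  sites <- data.frame(chrom = "chr1", pos = c(500L, 600L, 700L),
                      strand = c("+", "+", "-"),
                      status = "candidate", stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(500L, 600L, 700L),
                     ref = c("A", "A", "T"), alt = c("G", "T", "C"),
                     stringsAsFactors = FALSE)
  out <- exclude_snps(sites, snps)
  expect_equal(out$status, c("snp_excluded", "candidate", "snp_excluded"))
  expect_equal(exclude_snps(sites, NULL)$status, rep("candidate", 3))
})

test_that("recurrence is strictly more than the fraction of all samples", {
  cand <- data.frame(chrom = "chr1", pos = 100L, strand = "+",
                     n_ref = 90L, n_edit = 10L, n_other = 0L,
                     coverage = 100L, mismatch_rate = 0.1, beta = 0.1,
                     status = "candidate", stringsAsFactors = FALSE)
  none <- cand[0, ]
  counts1 <- data.table::data.table(chrom = "chr1", pos = 100L, A = 90L,
                                    C = 0L, G = 10L, T = 0L, ref = "A")
  mk <- function(k, n = 8) {
    per_sample <- c(rep(list(cand), k), rep(list(none), n - k))
    names(per_sample) <- paste0("s", seq_len(n))
    per_counts <- rep(list(counts1), n)
    names(per_counts) <- names(per_sample)
    recurrence_filter(per_sample, per_counts)
  }
  expect_equal(nrow(mk(4)$sites), 0L)   # 4/8 is not > 50%
  r5 <- mk(5)
  expect_equal(nrow(r5$sites), 1L)
  expect_equal(r5$sites$status, "high_confidence")
  # evidence gathered from every sample with coverage, candidate or not
  expect_equal(nrow(r5$evidence), 8L)
  expect_equal(nrow(mk(1, 1)$sites), 1L)    # degenerate single sample
  expect_error(recurrence_filter(list(), list()), "zero samples")
  # snp_excluded candidacies do not count towards recurrence
  snp <- cand; snp$status <- "snp_excluded"
  per_sample <- c(rep(list(cand), 4), rep(list(snp), 4))
  names(per_sample) <- paste0("s", 1:8)
  per_counts <- setNames(rep(list(counts1), 8), names(per_sample))
  expect_equal(nrow(recurrence_filter(per_sample, per_counts)$sites), 0L)
})

test_that("editing_level excludes other-base reads from the denominator", {
  expect_equal(editing_level(3L, 7L), 0.3)
  expect_equal(editing_level(0L, 20L), 0)
  expect_true(is.na(editing_level(0L, 0L)))
  expect_equal(editing_level(c(3L, 1L), c(7L, 0L)), c(0.3, 1))
})

test_that("overall_editing_level sums edited over total mapped reads", {
  ev <- data.frame(chrom = "chr1", pos = c(1L, 2L), strand = "+",
                   sample = "s1", n_ref = c(98L, 91L), n_edit = c(2L, 8L),
                   n_other = c(0L, 1L), coverage = c(100L, 100L),
                   beta = c(0.02, 8 / 99), stringsAsFactors = FALSE)
  expect_equal(overall_editing_level(ev, "s1"), 10 / 200)
  expect_true(is.na(overall_editing_level(ev, "s2")))
  one <- ev[1, ]
  expect_equal(overall_editing_level(one, "s1"), one$n_edit / one$coverage)
})

test_that("build_matrix lays out levels by stage order with missingness", {
  ev <- expand.grid(pos = c(10L, 20L, 30L), sample = c("e1", "e2"),
                    stringsAsFactors = FALSE)
  ev$chrom <- "chr1"; ev$strand <- "+"
  ev$n_ref <- 8L; ev$n_edit <- 2L; ev$n_other <- 0L; ev$coverage <- 10L
  ev$beta <- 0.2
  ev <- ev[!(ev$pos == 20 & ev$sample == "e1"), ]   # one missing cell
  m <- build_matrix(ev, c("e1", "e2"))
  expect_equal(dim(m$levels), c(3L, 2L))
  expect_true(m$missing["chr1:20:+", "e1"])
  expect_equal(sum(m$missing), 1L)
  expect_equal(m$levels["chr1:10:+", "e2"], 0.2)
})

test_that("tightening any threshold never adds a site", {
  corp <- random_mini_corpus(seed = 404)
  base_cfg <- filter_config(min_coverage = 10)
  call0 <- call_editing_sites(corp$sams, corp$genome, corp$snps, base_cfg,
                              dedup = FALSE)
  key0 <- paste(call0$sites$pos, call0$sites$strand)
  tighter <- list(
    filter_config(min_coverage = 10, min_base_quality = 30),
    filter_config(min_coverage = 10, min_mapq = 30),
    filter_config(min_coverage = 18),
    filter_config(min_coverage = 10, min_mismatch_rate = 0.1),
    filter_config(min_coverage = 10, max_third_allele_fraction = 0.005),
    filter_config(min_coverage = 10, recurrence_fraction = 0.8))
  for (cfg in tighter) {
    call1 <- call_editing_sites(corp$sams, corp$genome, corp$snps, cfg,
                                dedup = FALSE)
    expect_true(all(paste(call1$sites$pos, call1$sites$strand) %in% key0))
  }
})

test_that("cascade equals the brute-force oracle on a mini corpus", {
  corp <- random_mini_corpus(seed = 7)
  call <- call_editing_sites(corp$sams, corp$genome, corp$snps,
                             filter_config(), dedup = FALSE)
  oracle <- naive_cascade(corp$sams, corp$genome_chars, corp$snps)
  expect_identical(sort(paste0(call$sites$pos, call$sites$strand)),
                   oracle$sites)
  for (i in seq_len(nrow(call$evidence))) {
    ev <- call$evidence[i, ]
    okey <- paste(paste0(ev$pos, ev$strand), match(ev$sample, names(corp$sams)))
    oev <- oracle$evidence[[okey]]
    expect_equal(unname(oev),
                 c(ev$n_ref, ev$n_edit, ev$coverage))
  }
})
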