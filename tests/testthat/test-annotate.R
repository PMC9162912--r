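# Region precedence, recoding against an exhaustive codon-table oracle,
# repeat overlap, context composition and the rank-sum comparisons.


test_that("classify_recoding matches exhaustive codon enumeration", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  gc <- Biostrings::GENETIC_CODE   # independent oracle
  for (strand in c("+", "-")) {
    cds_seq <- paste0(codons, collapse = "")
    fx <- coding_fixture(cds_seq, strand)
    for (ci in seq_along(codons)) {
      codon <- codons[ci]
      for (off in 1:3) {
        if (substr(codon, off, off) != "A") next
        cds_index <- (ci - 1L) * 3L + off
        pos <- if (strand == "+") fx$cds_start + cds_index - 1L else
          fx$cds_start + fx$cds_len - cds_index
        rc <- classify_recoding("chr1", pos, fx$model, fx$genome)
        alt <- codon
        substr(alt, off, off) <- "G"
        expect_equal(rc$codon_ref, codon)
        expect_equal(rc$codon_alt, alt)
        expect_equal(rc$kind,
                     if (gc[[codon]] == gc[[alt]]) "synonymous"
                     else "nonsynonymous",
                     label = sprintf("codon %s offset %d strand %s",
                                     codon, off, strand))
      }
    }
  }
})

test_that("named recoding events come out as published", {
  fx <- coding_fixture("CAGTACGCAATG")
  # CAG -> CGG: Gln/Arg at codon position 2
  rc <- classify_recoding("chr1", fx$cds_start + 1L, fx$model, fx$genome)
  expect_equal(rc$label, "Q/R")
  expect_equal(rc$codon_alt, "CGG")
  # TAC -> TGC: Tyr/Cys
  rc <- classify_recoding("chr1", fx$cds_start + 4L, fx$model, fx$genome)
  expect_equal(rc$label, "Y/C")
  # GCA -> GCG: wobble, synonymous
  rc <- classify_recoding("chr1", fx$cds_start + 8L, fx$model, fx$genome)
  expect_equal(rc$kind, "synonymous")
  expect_equal(rc$label, "A/A")
  # minus-strand gene: coding ATA, genomic T>C at its first position -> I/V
  fx <- coding_fixture("ATAGGG", strand = "-")
  pos <- fx$cds_start + fx$cds_len - 1L   # coding index 1
  expect_equal(as.character(Biostrings::subseq(fx$genome$chr1, pos, pos)), "T")
  rc <- classify_recoding("chr1", pos, fx$model, fx$genome)
  expect_equal(rc$label, "I/V")
  expect_equal(rc$codon_alt, "GTA")
})

test_that("classify_recoding refuses non-coding situations gracefully", {
  fx <- coding_fixture("CAGTAA")
  rc <- classify_recoding("chr1", 5L, fx$model, fx$genome)  # outside CDS
  expect_equal(rc$kind, "not_coding")
  bad <- fx$model; bad$codable <- FALSE
  expect_equal(classify_recoding("chr1", fx$cds_start, bad, fx$genome)$kind,
               "not_coding")
})

test_that("assign_region follows the precedence order and is order-stable", {
  # gene A: 3'UTR 100..200; gene B: exon 50..80 + 250..300, intron between
  ga <- gene_model_fixture("geneA", "chr1", "+",
                           exons = data.frame(start = 100L, end = 200L),
                           cds = data.frame(start = 100L, end = 120L,
                                            frame = 0L),
                           utr3 = data.frame(start = 121L, end = 200L))
  ga$codable <- TRUE
  gb <- gene_model_fixture("geneB", "chr1", "+",
                           exons = data.frame(start = c(50L, 250L),
                                              end = c(80L, 300L)),
                           cds = data.frame(start = c(50L, 250L),
                                            end = c(80L, 300L),
                                            frame = c(0L, 0L)))
  sites <- data.frame(chrom = "chr1",
                      pos = c(110L, 150L, 60L, 220L, 400L),
                      stringsAsFactors = FALSE)
  out <- assign_region(sites, list(geneA = ga, geneB = gb))
  # 150 is utr3 of A and intron of B: utr3 wins
  expect_equal(out$region,
               c("exonic_cds", "utr3", "exonic_cds", "intronic", "intergenic"))
  expect_equal(out$gene_id, c("geneA", "geneA", "geneB", "geneB", NA))
  out2 <- assign_region(sites, list(geneB = gb, geneA = ga))
  expect_identical(out, out2)
  # ncRNA beats intronic; ties broken lexicographically
  gnc <- gene_model_fixture("aaNC", "chr1", "+",
                            exons = data.frame(start = 140L, end = 260L))
  out3 <- assign_region(data.frame(chrom = "chr1", pos = 220L),
                        list(geneB = gb, aaNC = gnc))
  expect_equal(out3$region, "ncRNA")
  expect_equal(out3$gene_id, "aaNC")
})

test_that("overlap_repeats picks the innermost repeat", {
  repeats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(100L, 150L, 500L),
                             end = c(600L, 280L, 550L)))
  S4Vectors::mcols(repeats)$family <- c("LINE", "SINE", "SINE")
  S4Vectors::mcols(repeats)$subfamily <- c("L1", "B1", "B2")
  out <- overlap_repeats(
    data.frame(chrom = "chr1", pos = c(200L, 520L, 400L, 900L)), repeats)
  expect_equal(out$repeat_subfamily, c("B1", "B2", "L1", NA))
  expect_equal(out$repeat_family, c("SINE", "SINE", "LINE", NA))
})

test_that("context_matrix takes 11-mers from the edited strand", {
  genome <- make_genome(list(chr1 = "CCCCCGACGTATGCACCCCC"))
  #                     pos:  12345678901234567890
  # site at 11 (A), plus strand: 6..16 = GACGTATGCAC
  cm <- context_matrix(data.frame(chrom = "chr1", pos = 11L, strand = "+"),
                       genome)
  expect_equal(cm$n_sites, 1L)
  expect_equal(cm$freq["A", "0"], 1)
  eleven <- strsplit("GACGTATGCAC", "")[[1]]
  for (i in seq_along(eleven))
    expect_equal(cm$counts[eleven[i], i], 1L)
  # minus strand at a genomic T: reverse complement makes centre A
  cm2 <- context_matrix(data.frame(chrom = "chr1", pos = 10L, strand = "-"),
                        genome)
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CGACGTATGCA"))), "")[[1]]
  expect_equal(cm2$freq["A", "0"], 1)
  for (i in seq_along(rc)) expect_equal(cm2$counts[rc[i], i], 1L)
  # near-edge site is skipped and counted
  cm3 <- context_matrix(data.frame(chrom = "chr1", pos = c(3L, 11L),
                                   strand = "+"), genome)
  expect_equal(cm3$n_skipped, 1L)
  expect_equal(cm3$n_sites, 1L)
  expect_equal(colSums(cm3$freq), rep(1, 11), ignore_attr = TRUE)
})

test_that("rank_sum_test reproduces the worked example and degenerate cases", {
  t <- rank_sum_test(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(t$U, 9)
  expect_equal(t$W, 15)
  expect_equal(t$p_value, 0.1)   # 2 of 20 assignments as extreme
  expect_equal(t$method, "exact")
  t1 <- rank_sum_test(1, 2)
  expect_equal(t1$method, "exact")
  expect_equal(t1$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "empty group")
  # ties or large groups fall back to the corrected normal approximation
  expect_equal(rank_sum_test(c(1, 1, 2), c(1, 2, 2))$method, "normal")
  expect_equal(rank_sum_test(rnorm(20), rnorm(20))$method, "normal")
})

test_that("exact rank-sum null is calibrated at the 5% level", {
  set.seed(1234)
  reject <- vapply(1:400, function(i) {
    x <- runif(6); y <- runif(6)
    rank_sum_test(x, y)$p_value <= 0.05
  }, TRUE)
  expect_lte(mean(reject), 0.06)
  expect_gte(mean(!reject), 0.94)
})

test_that("compare_levels_by_repeat splits classes and flags empty ones", {
  sites <- data.frame(
    repeat_family = c("SINE", "SINE", "SINE", "LINE", NA, NA, NA),
    repeat_subfamily = c("B1", "B1", "B1", "L1", NA, NA, NA),
    mean_level = c(0.5, 0.6, 0.7, 0.15, 0.1, 0.2, 0.3),
    stringsAsFactors = FALSE)
  out <- compare_levels_by_repeat(sites)
  expect_equal(lengths(out$levels), c(B1 = 3L, other_repeat = 1L,
                                      non_repeat = 3L))
  expect_equal(out$tests$p_value[out$tests$comparison == "B1_vs_non_repeat"],
               0.1)
  no_rep <- sites[sites$repeat_family %in% "SINE" | is.na(sites$repeat_family), ]
  out2 <- compare_levels_by_repeat(no_rep)
  expect_equal(out2$tests$method[1], "skipped_empty_class")
})

test_that("annotate_sites assembles all annotation columns", {
  run <- shared_small_run()
  corpus <- file.path(run$dir, "corpus")
  ann <- read_site_table(file.path(run$dir, "analysis", "annotated_sites.tsv"))
  truth <- run$truth
  m <- match(paste(ann$chrom, ann$pos), paste(truth$sites$chrom, truth$sites$pos))
  planted <- !is.na(m)
  # compartment-level agreement for planted, recovered sites
  comp <- truth$sites$compartment[m[planted]]
  expect_true(all(ann$region[planted][comp == "cds"] == "exonic_cds"))
  expect_true(all(ann$region[planted][comp == "utr3"] == "utr3"))
  expect_true(all(ann$repeat_subfamily[planted][comp == "b1"] == "B1"))
  expect_true(all(ann$recoding[planted][comp == "cds"] == "nonsynonymous"))
  expect_true(all(ann$region[planted][comp == "intergenic"] == "intergenic"))
  # region fractions over all sites sum to 1
  frac <- table(ann$region) / nrow(ann)
  expect_equal(sum(frac), 1)
})
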