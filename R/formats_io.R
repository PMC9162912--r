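# Readers/writers for the external formats the pipeline touches: SAM text,
# FASTA, sites-only VCF, a GTF subset, BED6+2 repeat tables and the TSV site
# tables the pipeline emits. All user-facing coordinates are 1-based.

SAM_FLAG_UNMAPPED      <- 0x4L
SAM_FLAG_REVERSE       <- 0x10L
SAM_FLAG_SECONDARY     <- 0x100L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

#' Parse a SAM file into a read table
#'
#' Reads a text SAM file and returns one row per mapped primary alignment.
#' Unmapped, secondary and supplementary records are skipped. The cell
#' barcode is taken from the tag named by `barcode_tag` (`NA` when absent).
#'
#' @param path Path to a SAM file (text, with header).
#' @param barcode_tag SAM tag carrying the cell barcode (default `"CB"`).
#' @param dedup If `TRUE`, collapse presumed PCR duplicates by keeping the
#'   first read per (chrom, leftmost position, orientation, CIGAR) key.
#'   Defaults to `FALSE`; the site-calling driver turns it on.
#' @return A `data.frame` with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`, `qual` (ASCII-33 string)
#'   and `barcode`.
#' @export
parse_alignments <- function(path, barcode_tag = "CB", dedup = FALSE) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "@"))
    stopf("SAM file %s has no header", path)
  body_idx <- which(!startsWith(lines, "@"))
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), barcode = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stopf("truncated SAM record at line %d of %s (%d fields)",
          body_idx[bad], path, nf[bad])
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  tag_prefix <- paste0(barcode_tag, ":Z:")
  barcode <- vapply(fields, function(f) {
    if (length(f) > 11L) {
      hit <- f[startsWith(f, tag_prefix)]
      if (length(hit)) return(substring(hit[[1L]], nchar(tag_prefix) + 1L))
    }
    NA_character_
  }, "")
  reads <- data.frame(
    qname = vapply(fields, `[[`, "", 1L),
    flag = flag,
    chrom = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[[`, "", 5L)),
    cigar = vapply(fields, `[[`, "", 6L),
    seq = vapply(fields, `[[`, "", 10L),
    qual = vapply(fields, `[[`, "", 11L),
    barcode = barcode,
    stringsAsFactors = FALSE)
  drop <- bitwAnd(reads$flag, SAM_FLAG_UNMAPPED + SAM_FLAG_SECONDARY +
                    SAM_FLAG_SUPPLEMENTARY) != 0L
  reads <- reads[!drop, , drop = FALSE]
  rownames(reads) <- NULL
  if (dedup) reads <- dedup_reads(reads)
  reads
}

#' Remove presumed PCR-duplicate reads
#'
#' Keeps the first read per (chrom, leftmost position, orientation, CIGAR)
#' key, a deterministic stand-in for external clonal-read removal.
#'
#' @param reads Read table from [parse_alignments()].
#' @return The deduplicated read table.
#' @export
dedup_reads <- function(reads) {
  key <- paste(reads$chrom, reads$pos,
               bitwAnd(reads$flag, SAM_FLAG_REVERSE), reads$cigar, sep = "\r")
  out <- reads[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Walk one CIGAR string: returns the 1-based reference coordinate of every
# query base, NA for query bases that do not align to the reference (I, S).
# M/=/X consume both; I/S consume query only; D/N consume reference only;
# H/P consume neither.
#' @noRd
cigar_ref_positions <- function(cigar, pos) {
  if (cigar == "*") stopf("missing CIGAR ('*') for mapped read at pos %d", pos)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || sum(nchar(ops)) != nchar(cigar))
    stopf("malformed CIGAR: %s", cigar)
  n <- as.integer(substr(ops, 1L, nchar(ops) - 1L))
  op <- substr(ops, nchar(ops), nchar(ops))
  out <- vector("list", length(ops))
  ref <- pos
  for (i in seq_along(ops)) {
    if (op[i] %in% c("M", "=", "X")) {
      out[[i]] <- seq.int(ref, length.out = n[i])
      ref <- ref + n[i]
    } else if (op[i] %in% c("I", "S")) {
      out[[i]] <- rep(NA_integer_, n[i])
    } else if (op[i] %in% c("D", "N")) {
      ref <- ref + n[i]
    } # H, P: nothing
  }
  unlist(out, use.names = FALSE)
}

#' Expand reads to per-base records
#'
#' Reconstructs, from each read's CIGAR, the reference coordinate of every
#' aligned query base and returns one row per base. Soft-clipped and
#' inserted bases are dropped.
#'
#' @param reads Read table from [parse_alignments()].
#' @return A `data.table` with columns `chrom`, `pos` (1-based reference),
#'   `base`, `qual` (integer Phred), `mapq`, `barcode`, `read_id`.
#' @export
read_bases <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.table(chrom = character(), pos = integer(), base = character(),
                      qual = integer(), mapq = integer(),
                      barcode = character(), read_id = integer()))
  }
  len <- nchar(reads$seq)
  simple <- reads$cigar == paste0(len, "M")
  pos_list <- vector("list", nrow(reads))
  if (any(simple)) {
    w <- which(simple)
    pos_list[w] <- lapply(w, function(i) seq.int(reads$pos[i], length.out = len[i]))
  }
  if (any(!simple)) {
    w <- which(!simple)
    pos_list[w] <- lapply(w, function(i)
      cigar_ref_positions(reads$cigar[i], reads$pos[i]))
  }
  nb <- lengths(pos_list)
  if (any(nb != len))
    stopf("CIGAR/sequence length mismatch for read %s",
          reads$qname[which(nb != len)[1L]])
  idx <- rep.int(seq_len(nrow(reads)), nb)
  dt <- data.table(
    chrom = reads$chrom[idx],
    pos = unlist(pos_list, use.names = FALSE),
    base = unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE),
    qual = unlist(lapply(reads$qual, function(q) utf8ToInt(q) - 33L),
                  use.names = FALSE),
    mapq = reads$mapq[idx],
    barcode = reads$barcode[idx],
    read_id = idx)
  dt[!is.na(pos)]
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Vectorized single-base lookup, 1-based.
#' @noRd
genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stopf("chromosome %s absent from reference", ch)
    i <- chrom == ch
    s <- genome[[ch]]
    bad <- pos[i] < 1L | pos[i] > length(s)
    if (any(bad)) stopf("position out of range on %s", ch)
    out[i] <- strsplit(as.character(s), "")[[1L]][pos[i]]
  }
  out
}

# Faster lookup when positions are many: extract per-chromosome substrings.
#' @noRd
genome_bases_at <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stopf("chromosome %s absent from reference", ch)
    i <- which(chrom == ch)
    out[i] <- as.character(subseq(rep(genome[ch], length(i)),
                                  start = pos[i], end = pos[i]))
  }
  out
}

#' Parse gene models from a GTF file
#'
#' Supports the feature vocabulary `exon`, `CDS`, `five_prime_utr`,
#' `three_prime_utr` with a `gene_id` attribute (and optional `gene_name`).
#' A gene whose total CDS length is not divisible by 3 is flagged
#' non-codable with a warning; genes without CDS get region annotation only.
#'
#' @param path GTF file (1-based inclusive coordinates).
#' @return A named list of `gene_model` objects, each a list with elements
#'   `gene_id`, `gene_name`, `chrom`, `strand`, and `data.frame`s `exons`,
#'   `cds` (with `frame`), `utr5`, `utr3` (1-based closed intervals), plus
#'   logical `codable`.
#' @export
parse_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  ids <- unique(md$gene_id)
  models <- lapply(ids, function(id) {
    g <- gr[md$gene_id == id]
    gm <- S4Vectors::mcols(g)
    type <- as.character(gm$type)
    strand <- as.character(GenomicRanges::strand(g))[1L]
    iv <- function(sel) {
      gg <- g[sel]
      o <- order(GenomicRanges::start(gg))
      data.frame(start = GenomicRanges::start(gg)[o],
                 end = GenomicRanges::end(gg)[o])
    }
    cds <- iv(type == "CDS")
    if (nrow(cds)) {
      ph <- gm$phase[type == "CDS"]
      cds$frame <- as.integer(ph)[order(GenomicRanges::start(g[type == "CDS"]))]
      if (anyNA(cds$frame)) {
        # reconstruct frame along the transcription direction
        ord <- if (strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
        f <- 0L
        for (j in ord) {
          cds$frame[j] <- f
          f <- (3L - ((cds$end[j] - cds$start[j] + 1L - f) %% 3L)) %% 3L
        }
      }
    } else {
      cds$frame <- integer()
    }
    codable <- nrow(cds) > 0L
    if (codable) {
      total <- sum(cds$end - cds$start + 1L)
      if (total %% 3L != 0L) {
        warnf("gene %s: CDS length %d not divisible by 3; flagged non-codable",
              id, total)
        codable <- FALSE
      }
    }
    structure(list(
      gene_id = id,
      gene_name = if (!is.null(gm$gene_name)) as.character(gm$gene_name)[1L] else id,
      chrom = as.character(GenomicRanges::seqnames(g))[1L],
      strand = strand,
      exons = iv(type == "exon"),
      cds = cds,
      utr5 = iv(type == "five_prime_utr"),
      utr3 = iv(type == "three_prime_utr"),
      codable = codable), class = "gene_model")
  })
  names(models) <- ids
  models
}

#' Parse known SNPs from a sites-only VCF
#'
#' One record per ALT allele; multi-allelic rows are expanded. Rows with a
#' missing ALT are skipped with a warning.
#'
#' @param path VCF 4.x file (CHROM/POS/REF/ALT used).
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
parse_snps <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  alt_list <- lapply(VariantAnnotation::alt(vcf), as.character)
  n_alt <- lengths(alt_list)
  if (any(n_alt == 0L)) {
    warnf("%d VCF row(s) with missing ALT skipped", sum(n_alt == 0L))
  }
  idx <- rep.int(seq_along(rr), n_alt)
  alt <- unlist(alt_list, use.names = FALSE)
  keep <- !is.na(alt) & nzchar(alt) & alt != "."
  idx <- idx[keep]; alt <- alt[keep]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = alt,
    stringsAsFactors = FALSE)
}

#' Read a repeat annotation from BED6+2
#'
#' Expects BED6 plus two extra columns, `family` (SINE, LINE, LTR, DNA,
#' Simple_repeat, Other) and `subfamily` (free text, e.g. B1).
#'
#' @param path BED file.
#' @return A `GRanges` with metadata columns `family` and `subfamily`.
#' @export
read_repeats <- function(path) {
  rtracklayer::import(path, format = "bed",
                      extraCols = c(family = "character",
                                    subfamily = "character"))
}

REPEAT_FAMILIES <- c("SINE", "LINE", "LTR", "DNA", "Simple_repeat", "Other")

# Writers used by the simulator; plain text, deterministic field order.
#' @noRd
write_repeats_bed <- function(repeats_df, path) {
  # repeats_df: chrom, start (1-based), end, name, strand, family, subfamily
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%s",
                   repeats_df$chrom, repeats_df$start - 1L, repeats_df$end,
                   repeats_df$name, repeats_df$strand,
                   repeats_df$family, repeats_df$subfamily)
  writeLines(lines, path)
}

#' @noRd
write_snps_vcf <- function(snps, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                                  snps$chrom, snps$pos, snps$ref, snps$alt)
          else character()
  writeLines(c(header, body), path)
}

#' @noRd
format_number <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an annotated site table to TSV
#'
#' One row per site. Numeric columns are written at full precision so the
#' table round-trips losslessly through [read_site_table()].
#'
#' @param sites A `data.frame` of sites (any columns; `chrom`, `pos`,
#'   `strand` expected first).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- as.data.frame(sites)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_number(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return A `data.frame` with column types restored.
#' @export
read_site_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA", colClasses = "character",
                   check.names = FALSE)
  for (j in seq_along(df)) {
    df[[j]] <- utils::type.convert(df[[j]], as.is = TRUE)
  }
  df
}

#' @noRd
write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- format_number(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
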