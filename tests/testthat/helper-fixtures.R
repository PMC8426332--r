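# Fixture builders shared across test files. Everything is generated in
# code at test time; no binary fixtures are stored.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Write a FASTA file from a named character vector, return its path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# A designed single-transcript plus-strand gene: exon1 | intron | exon2 laid
# out on one contig starting at offset 50, with CDS spanning both exons.
# Returns genome (DNAStringSet), the gene_model, and the intron table.
designed_gene <- function(exon1, intron, exon2, strand = "+",
                          chrom = "chrT", offset = 50L) {
  tx <- paste0(exon1, intron, exon2)
  body <- if (strand == "+") tx else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  pad <- function(n) paste(rep("A", n), collapse = "")
  contig <- paste0(pad(offset), body, pad(20))
  genome <- Biostrings::DNAStringSet(setNames(contig, chrom))
  L <- nchar(tx)
  l1 <- nchar(exon1); li <- nchar(intron)
  tx_iv <- rbind(c(0L, l1), c(l1 + li, L))          # transcript coords
  gen_iv <- if (strand == "+") offset + tx_iv else
    offset + L - tx_iv[, 2:1, drop = FALSE]
  if (strand == "-") gen_iv <- gen_iv[, , drop = FALSE]
  exons <- cbind(start = as.integer(gen_iv[, 1]), end = as.integer(gen_iv[, 2]))
  if (strand == "-") exons <- exons  # transcription order already row 1 = 5'
  gm <- structure(list(gene_id = "gX", transcript_id = "gX.t1", chrom = chrom,
                       strand = strand, exons = exons, cds = exons),
                  class = "gene_model")
  list(genome = genome, gene = gm, introns = extract_introns(gm))
}

# Brute-force peptide oracle: every substring of every length in k_range of
# flank+intron, kept iff it overlaps the intronic suffix, deduplicated.
oracle_peptides <- function(flank, intron_aa, k_range = 8:11) {
  s <- paste0(flank, intron_aa)
  f <- nchar(flank); n <- nchar(s)
  out <- character(0)
  for (k in k_range) {
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      if (i + k - 1 > f) out <- c(out, substr(s, i, i + k - 1))
    }
  }
  unique(out)
}

# Closed-form window count (pre-dedup) for flank f, intronic m.
closed_form_windows <- function(f, m, k_range = 8:11) {
  sum(vapply(k_range, function(k)
    max(0, f + m - k + 1) - max(0, f - k + 1), 0))
}

# Minimal intron model table for quantification tests: one event per row,
# all on one contig, regions laid end-to-end so nothing is shared.
quant_introns <- function(n = 1L, intron_len = 100L, exon_len = 200L) {
  step <- 2L * exon_len + intron_len
  start <- (seq_len(n) - 1L) * (step + 50L)
  up_s <- start; up_e <- up_s + exon_len
  in_s <- up_e; in_e <- in_s + intron_len
  dn_s <- in_e; dn_e <- dn_s + exon_len
  data.frame(
    event_id = event_id_of("chrQ", in_s, in_e, "+",
                           paste0("t", seq_len(n))),
    gene_id = paste0("g", seq_len(n)), transcript_id = paste0("t", seq_len(n)),
    chrom = "chrQ", strand = "+", intron_start = in_s, intron_end = in_e,
    up_start = up_s, up_end = up_e, down_start = dn_s, down_end = dn_e,
    frame = 0L, stringsAsFactors = FALSE)
}

# Region counts row(s) matching quant_introns().
quant_counts <- function(introns, intron_count, up_count, down_count,
                         library_size = NULL) {
  n <- nrow(introns)
  lib <- library_size %||% sum(intron_count, up_count, down_count)
  data.frame(event_id = introns$event_id,
             intron_count = rep_len(intron_count, n),
             up_count = rep_len(up_count, n),
             down_count = rep_len(down_count, n),
             library_size = lib, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exponential two-group survival data with a known hazard ratio.
sim_survival <- function(n_per_arm, hr, censor_rate = 0.3, base = 0.02) {
  group <- rep(c("A", "B"), each = n_per_arm)
  hz <- ifelse(group == "B", base * hr, base)
  t_ev <- rexp(2 * n_per_arm, hz)
  if (censor_rate > 0) {
    t_c <- rexp(2 * n_per_arm, base * censor_rate / (1 - censor_rate))
    data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
               group = group, x = as.numeric(group == "B"))
  } else {
    data.frame(time = t_ev, event = 1L, group = group,
               x = as.numeric(group == "B"))
  }
}

# Write a tiny SAM file and convert to BAM+BAI; returns the BAM path.
# reads: data.frame(qname, pos (1-based), mapq, cigar, nh (NA = omit tag))
sam_to_bam <- function(reads, chrom = "chrT", contig_len = 1000L) {
  sam <- tempfile(fileext = ".sam")
  mlen <- function(cig) {
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MI=X]", ops)])))
  }
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, contig_len))
  reads <- reads[order(reads$pos), , drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    seq <- paste(rep("A", mlen(r$cigar)), collapse = "")
    fields <- c(r$qname, 0L, chrom, r$pos, r$mapq, r$cigar, "*", 0L, 0L,
                seq, "*")
    if (!is.na(r$nh)) fields <- c(fields, paste0("NH:i:", r$nh))
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# Brute-force read counter independent of GenomicAlignments: aligned block
# intervals from the CIGAR (0-based half-open), >= 1 bp overlap rule.
oracle_count <- function(reads, region_start, region_end, mapq_unique = 255L) {
  hits <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    uniq <- if (!is.na(r$nh)) r$nh == 1L else r$mapq >= mapq_unique
    if (!uniq) next
    pos <- r$pos - 1L
    ops <- regmatches(r$cigar, gregexpr("\\d+[MIDNSHP=X]", r$cigar))[[1]]
    cur <- pos; overlap <- FALSE
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        if (max(cur, region_start) < min(cur + n, region_end)) overlap <- TRUE
        cur <- cur + n
      } else if (type %in% c("D", "N")) cur <- cur + n
    }
    if (overlap) hits <- hits + 1L
  }
  hits
}
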