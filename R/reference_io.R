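#' Reference I/O: annotation, genome, proteome
#'
#' Parsers and model builders for the reference inputs of the IR-neoantigen
#' pipeline. All internal coordinates are 0-based half-open; GTF conversion
#' (1-based inclusive) happens only at the file boundary.
#'
#' @name reference_io
NULL

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Load a genome FASTA
#'
#' @param fasta_path path to a (possibly multi-contig) nucleotide FASTA
#' @return a [Biostrings::DNAStringSet] keyed by contig name
#' @export
read_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions; key by the first token
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
  genome
}

#' Extract a strand-aware region sequence
#'
#' Coordinates are 0-based half-open genomic; minus-strand regions are
#' reverse-complemented so the result reads in transcription order.
#' @param genome DNAStringSet from [read_genome()]
#' @param chrom contig name
#' @param start,end 0-based half-open interval
#' @param strand "+" or "-"
#' @return character scalar
#' @export
region_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("contig not present in genome FASTA: ", chrom)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Load gene models from a GTF annotation
#'
#' Builds one model per transcript with at least one exon. Exons and CDS are
#' stored in transcription order (reversed genomic order on the minus strand)
#' as 0-based half-open intervals. Transcripts whose CDS intervals are not
#' nested inside exons are skipped with a warning; a contig referenced by the
#' GTF but absent from the FASTA is a hard error.
#'
#' @param gtf_path path to an Ensembl/Gencode-dialect GTF (attributes
#'   `gene_id`, `transcript_id`; features `exon` and optionally `CDS`)
#' @param fasta_path genome FASTA covering all referenced contigs
#' @return list of `gene_model` objects (fields: gene_id, transcript_id,
#'   chrom, strand, exons, cds — both interval matrices with columns
#'   start/end, in transcription order)
#' @export
load_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome_names <- names(read_genome(fasta_path))
  used <- unique(as.character(GenomicRanges::seqnames(gr)))
  missing <- setdiff(used, genome_names)
  if (length(missing))
    stop("contig(s) referenced by GTF but absent from FASTA: ",
         paste(missing, collapse = ", "))
  feat <- as.character(gr$type)
  keep <- feat %in% c("exon", "CDS")
  gr <- gr[keep]; feat <- feat[keep]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = feat,
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE)
  models <- list()
  for (tx in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tx, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) next
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    strand <- ex$strand[1]
    ord <- order(ex$start)
    if (strand == "-") ord <- rev(ord)
    ex <- ex[ord, , drop = FALSE]
    exons <- cbind(start = ex$start, end = ex$end)
    cds_m <- NULL
    if (nrow(cds)) {
      ordc <- order(cds$start)
      if (strand == "-") ordc <- rev(ordc)
      cds <- cds[ordc, , drop = FALSE]
      nested <- vapply(seq_len(nrow(cds)), function(i) {
        any(cds$start[i] >= exons[, "start"] & cds$end[i] <= exons[, "end"])
      }, logical(1))
      if (!all(nested)) {
        warning("transcript ", tx, ": CDS not nested in exons; skipped")
        next
      }
      cds_m <- cbind(start = cds$start, end = cds$end)
    }
    models[[tx]] <- structure(
      list(gene_id = ex$gene_id[1], transcript_id = tx, chrom = ex$chrom[1],
           strand = strand, exons = exons,
           cds = cds_m %||% cbind(start = integer(0), end = integer(0))),
      class = "gene_model")
  }
  unname(models)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s  %s(%s)  %d exon(s), %d CDS segment(s)\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Extract intron models from a gene model
#'
#' Each gap between consecutive exons (transcription order) becomes one
#' intron with its upstream (5') and downstream (3') flanking exons.
#' `frame` gives the number of coding nucleotides of the codon spanning the
#' exon/intron junction that already lie in the exon, i.e. cumulative CDS
#' length upstream of the junction mod 3. It is NA when the upstream exon's
#' CDS does not extend to the junction (non-coding or 3'-UTR junctions).
#'
#' @param gene a `gene_model`
#' @return data.frame with one row per intron: event_id, gene_id,
#'   transcript_id, chrom, strand, intron_start/end, up_start/end,
#'   down_start/end (genomic 0-based half-open), frame
#' @export
extract_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nrow(gene$exons)
  empty <- data.frame(event_id = character(0), gene_id = character(0),
                      transcript_id = character(0), chrom = character(0),
                      strand = character(0), intron_start = integer(0),
                      intron_end = integer(0), up_start = integer(0),
                      up_end = integer(0), down_start = integer(0),
                      down_end = integer(0), frame = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  rows <- vector("list", n - 1L)
  cum_cds <- cumulative_cds(gene)
  for (i in seq_len(n - 1L)) {
    up <- gene$exons[i, ]; down <- gene$exons[i + 1L, ]
    if (gene$strand == "+") {
      istart <- up[["end"]]; iend <- down[["start"]]
    } else {
      istart <- down[["end"]]; iend <- up[["start"]]
    }
    if (iend - istart < 1L) {
      warning("transcript ", gene$transcript_id,
              ": zero-length gap after exon ", i, "; junction skipped")
      next
    }
    rows[[i]] <- data.frame(
      event_id = event_id_of(gene$chrom, istart, iend, gene$strand,
                             gene$transcript_id),
      gene_id = gene$gene_id, transcript_id = gene$transcript_id,
      chrom = gene$chrom, strand = gene$strand,
      intron_start = istart, intron_end = iend,
      up_start = up[["start"]], up_end = up[["end"]],
      down_start = down[["start"]], down_end = down[["end"]],
      frame = cum_cds[i], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Per exon i (transcription order): cumulative CDS nt through exon i mod 3,
# or NA when the exon's CDS does not reach its junction-side boundary.
cumulative_cds <- function(gene) {
  n <- nrow(gene$exons)
  out <- rep(NA_integer_, n)
  if (nrow(gene$cds) == 0L) return(out)
  total <- 0L
  for (i in seq_len(n)) {
    ex <- gene$exons[i, ]
    ov_start <- pmax(gene$cds[, "start"], ex[["start"]])
    ov_end <- pmin(gene$cds[, "end"], ex[["end"]])
    ov_len <- pmax(0L, ov_end - ov_start)
    hit <- which(ov_len > 0L)
    total <- total + sum(ov_len)
    if (length(hit) != 1L) next
    # junction-side boundary: genomic end on +, genomic start on -
    reaches <- if (gene$strand == "+")
      gene$cds[hit, "end"] >= ex[["end"]]
    else gene$cds[hit, "start"] <= ex[["start"]]
    if (reaches) out[i] <- as.integer(total %% 3L)
  }
  out
}

#' Extract introns for a list of gene models
#'
#' @param genes list of `gene_model`
#' @param dedupe if TRUE, keep one row per unique genomic interval
#'   (chrom, start, end, strand) — the first transcript seen wins
#' @return combined intron model data.frame (see [extract_introns()])
#' @export
extract_all_introns <- function(genes, dedupe = FALSE) {
  out <- do.call(rbind, lapply(genes, extract_introns))
  if (is.null(out) || nrow(out) == 0L) return(out)
  rownames(out) <- NULL
  if (dedupe) {
    key <- paste(out$chrom, out$intron_start, out$intron_end, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build an exact-match self-peptide index from a proteome FASTA
#'
#' Indexes every k-mer (k = 8..11 by default) over the 20 standard amino
#' acids; windows containing non-standard residues (B, J, O, U, X, Z, *) are
#' not indexed. Matching is case-insensitive (sequences are upper-cased).
#'
#' @param proteome_fasta path to an amino-acid FASTA
#' @param k_range integer vector of k-mer lengths
#' @return a `proteome_index` (list of per-k unique k-mer vectors)
#' @export
build_proteome_index <- function(proteome_fasta, k_range = 8:11) {
  aa <- Biostrings::readAAStringSet(proteome_fasta)
  if (length(aa) == 0L) stop("empty proteome FASTA: ", proteome_fasta)
  seqs <- toupper(as.character(aa))
  kmers <- lapply(k_range, function(k) {
    out <- lapply(seqs, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      ok <- strsplit(s, "")[[1]] %in% STANDARD_AA
      # a window [i, i+k-1] is clean iff it contains k standard residues
      run <- cumsum(ok)
      starts <- seq_len(L - k + 1L)
      clean <- (run[starts + k - 1L] - c(0L, run)[starts]) == k
      if (!any(clean)) return(character(0))
      substring(s, starts[clean], starts[clean] + k - 1L)
    })
    unique(unlist(out, use.names = FALSE))
  })
  structure(list(k_range = k_range, kmers = setNames(kmers, k_range)),
            class = "proteome_index")
}

#' Query a proteome index
#'
#' @param index a `proteome_index`
#' @param peptides character vector (lengths must be within the indexed
#'   k range)
#' @return logical vector: is each peptide an exact substring of the proteome
#' @export
peptide_in_proteome <- function(index, peptides) {
  stopifnot(inherits(index, "proteome_index"))
  if (!length(peptides)) return(logical(0))
  pep <- toupper(peptides)
  k <- nchar(pep)
  if (any(!k %in% index$k_range))
    stop("peptide length outside indexed k range: ",
         paste(unique(k[!k %in% index$k_range]), collapse = ", "))
  out <- logical(length(pep))
  for (kk in unique(k)) {
    sel <- k == kk
    out[sel] <- pep[sel] %in% index$kmers[[as.character(kk)]]
  }
  out
}

#' Write intron models as BED6
#'
#' BED is natively 0-based half-open, matching internal coordinates.
#' @param introns intron model data.frame
#' @param path output file
#' @export
write_intron_bed <- function(introns, path) {
  bed <- data.frame(introns$chrom, introns$intron_start, introns$intron_end,
                    introns$event_id, 0L, introns$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GTF
#'
#' Inverse of [load_annotation()] (coordinates converted back to 1-based
#' inclusive); used by the synthetic generator and for round-trip checks.
#' @param genes list of `gene_model`
#' @param path output file
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        g$gene_id, g$transcript_id)
    fmt <- function(type, m) {
      if (nrow(m) == 0L) return(character(0))
      sprintf("%s\tneoIR\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, m[, "start"] + 1L, m[, "end"], g$strand, attr_str)
    }
    lines <- c(lines, fmt("exon", g$exons), fmt("CDS", g$cds))
  }
  writeLines(lines, path)
  invisible(path)
}
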