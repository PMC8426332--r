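#' Neoantigen calling from retained introns
#'
#' Retained introns are translated by extending the upstream exon's open
#' reading frame through the intron with the standard codon table, stopping
#' at the first in-frame stop codon. Translations are segmented into
#' 8-11-mers containing at least one intron-encoded residue, self-peptides
#' are removed against the proteome index, and MHC class I binders are
#' called at percentile rank < 2 through a pluggable predictor.
#'
#' @name neoantigen
NULL

#' Translate one retained intron by ORF extension
#'
#' Translation starts at the last complete codon boundary inside the
#' upstream exon (at most `max_flank_aa` exonic residues are retained) and
#' proceeds codon by codon into the intron, in transcription order, stopping
#' at the first in-frame stop codon or at the last complete codon the intron
#' can supply. A codon spanning the junction counts as intron-encoded (it
#' uses at least one intronic nucleotide). A codon containing an ambiguous
#' base truncates the translation at that codon. Stop codons upstream of the
#' junction (e.g. UTR sequence drawn into the flank window) trim the exonic
#' flank to the residues after the last stop, so the returned concatenation
#' never contains a stop symbol.
#'
#' @param intron one row of an intron model data.frame; `frame` must not be
#'   NA (non-coding upstream exons are not translatable)
#' @param genome DNAStringSet from [read_genome()]
#' @param max_flank_aa exonic residues kept 5' of the junction (default 10,
#'   i.e. max peptide length - 1)
#' @return one-row data.frame: event_id, exon_flank_aa, intron_aa,
#'   terminated_by_stop
#' @export
translate_extension <- function(intron, genome, max_flank_aa = 10L) {
  if (is.na(intron$frame))
    stop("event ", intron$event_id,
         ": upstream exon is non-coding at the junction; cannot extend ORF")
  r <- as.integer(intron$frame)
  exon_seq <- region_seq(genome, intron$chrom, intron$up_start,
                         intron$up_end, intron$strand)
  n_exon <- nchar(exon_seq)
  partial <- if (r > 0L) substr(exon_seq, n_exon - r + 1L, n_exon) else ""
  n_flank <- min(max_flank_aa, (n_exon - r) %/% 3L)
  flank_nt <- if (n_flank > 0L)
    substr(exon_seq, n_exon - r - 3L * n_flank + 1L, n_exon - r) else ""
  fl <- translate_codons(flank_nt, stop_at_stop = FALSE)
  flank_aa <- fl$aa
  if (fl$stopped) {
    # keep only residues downstream of the last stop
    parts <- strsplit(paste0(fl$aa_with_stops, "|"), "\\*")[[1]]
    flank_aa <- sub("\\|$", "", parts[length(parts)])
  }
  intron_seq <- region_seq(genome, intron$chrom, intron$intron_start,
                           intron$intron_end, intron$strand)
  ext <- translate_codons(paste0(partial, intron_seq))
  data.frame(event_id = intron$event_id, exon_flank_aa = flank_aa,
             intron_aa = ext$aa, terminated_by_stop = ext$stopped,
             stringsAsFactors = FALSE)
}

# Codon-by-codon translation of complete codons. With stop_at_stop the
# first stop codon terminates (and is excluded); otherwise all codons are
# translated and stops are retained in aa_with_stops. A codon with an
# ambiguous base truncates either way.
translate_codons <- function(nt, stop_at_stop = TRUE) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  aa <- character(0); all_aa <- character(0); stopped <- FALSE
  gc_tab <- Biostrings::GENETIC_CODE
  if (n > 0L) for (i in seq_len(n)) {
    codon <- substr(nt, 3L * i - 2L, 3L * i)
    res <- unname(gc_tab[codon])
    if (is.na(res)) {
      message("ambiguous base in codon '", codon, "'; translation truncated")
      break
    }
    all_aa <- c(all_aa, res)
    if (res == "*") {
      stopped <- TRUE
      if (stop_at_stop) break else next
    }
    aa <- c(aa, res)
  }
  list(aa = paste(aa, collapse = ""),
       aa_with_stops = paste(all_aa, collapse = ""), stopped = stopped)
}

#' Translate all retained introns of an event table
#'
#' Events whose upstream exon is non-coding at the junction are skipped with
#' a message.
#' @param introns intron model data.frame (typically subset to called
#'   events)
#' @param genome DNAStringSet
#' @param max_flank_aa see [translate_extension()]
#' @return data.frame of extended translations, one row per translatable
#'   event
#' @export
translate_all <- function(introns, genome, max_flank_aa = 10L) {
  keep <- !is.na(introns$frame)
  if (any(!keep))
    message(sum(!keep), " event(s) skipped: non-coding upstream exon")
  rows <- lapply(which(keep), function(i)
    translate_extension(introns[i, ], genome, max_flank_aa))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), exon_flank_aa = character(0),
               intron_aa = character(0), terminated_by_stop = logical(0))
  rownames(out) <- NULL
  out
}

#' Enumerate candidate neoepitopes from extended translations
#'
#' All length-k windows (k in `k_range`) of `exon_flank_aa + intron_aa`
#' containing at least one intron-encoded residue, deduplicated by
#' (peptide, event_id).
#'
#' @param translations data.frame from [translate_all()] (or a single row
#'   from [translate_extension()])
#' @param k_range peptide lengths (default 8:11)
#' @return data.frame: peptide, event_id, n_intronic, length
#' @export
enumerate_peptides <- function(translations, k_range = 8:11) {
  out <- lapply(seq_len(nrow(translations)), function(i) {
    fl <- translations$exon_flank_aa[i]
    ia <- translations$intron_aa[i]
    f <- nchar(fl); m <- nchar(ia)
    seqc <- paste0(fl, ia)
    rows <- lapply(k_range, function(k) {
      n_win <- f + m - k + 1L
      if (n_win < 1L) return(NULL)
      starts <- seq_len(n_win)
      # intron-encoded residues occupy positions f+1 .. f+m
      n_intronic <- pmax(0L, pmin(starts + k - 1L, f + m) - pmax(starts, f + 1L) + 1L)
      keep <- n_intronic >= 1L
      if (!any(keep)) return(NULL)
      data.frame(peptide = substring(seqc, starts[keep], starts[keep] + k - 1L),
                 event_id = translations$event_id[i],
                 n_intronic = n_intronic[keep], length = k,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(peptide = character(0), event_id = character(0),
                      n_intronic = integer(0), length = integer(0)))
  res <- res[!duplicated(paste(res$peptide, res$event_id)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove self-peptides
#'
#' Exact-match removal of any candidate also generated by normal proteins:
#' a peptide present verbatim in the proteome k-mer index is dropped.
#' Idempotent and order-independent.
#'
#' @param peptides data.frame from [enumerate_peptides()]
#' @param index a `proteome_index`
#' @return `peptides` subset to non-self rows, with an `is_self` column
#'   (all FALSE)
#' @export
filter_self <- function(peptides, index) {
  if (!nrow(peptides)) {
    peptides$is_self <- logical(0)
    return(peptides)
  }
  is_self <- peptide_in_proteome(index, peptides$peptide)
  out <- peptides[!is_self, , drop = FALSE]
  out$is_self <- FALSE
  rownames(out) <- NULL
  out
}

#' Normalize an HLA class I allele name to two-field resolution
#'
#' `"HLA-A*02:01"`, `"A*02:01:05"`, and `"A02:01"` all map to `"A02:01"`.
#' @param x character vector of allele names
#' @return character vector of canonical two-field names (gene + 2 fields)
#' @export
normalize_hla <- function(x) {
  y <- toupper(gsub("\\s", "", x))
  y <- sub("^HLA-", "", y)
  y <- gsub("\\*", "", y)
  m <- regexec("^([A-Z]+[0-9]?)([0-9]{2,3}):([0-9]{2,3})", y)
  ok <- vapply(regmatches(y, m), length, 0L) == 4L
  if (any(!ok)) stop("unparseable HLA allele(s): ",
                     paste(unique(x[!ok]), collapse = ", "))
  vapply(regmatches(y, m), function(p) paste0(p[2], p[3], ":", p[4]), "")
}

#' Per-sample neoantigen load
#'
#' `neoag_load` counts unique binder peptides (deduplicated across alleles
#' and source events); `weighted_load` sums, over neoantigen-producing
#' events, the event's intron RPKM times its number of unique binder
#' peptides (a peptide produced by several events contributes to each). The
#' `load_unit = "peptide-allele"` alternative counts (peptide, allele)
#' binder pairs instead; `weighted_mode = "rpkm_once"` sums each producing
#' event's RPKM a single time.
#'
#' @param calls binding calls data.frame (see [predict_binding()])
#' @param quant per-sample filtered quantification records (RPKM source)
#' @param peptides peptide table linking peptides to source events
#' @param sample_id label for the output row
#' @param load_unit "peptide" (default) or "peptide-allele"
#' @param weighted_mode "per_peptide" (default) or "rpkm_once"
#' @return one-row data.frame: sample_id, n_events, neoag_load,
#'   weighted_load
#' @export
compute_sample_load <- function(calls, quant, peptides, sample_id = "sample",
                                load_unit = c("peptide", "peptide-allele"),
                                weighted_mode = c("per_peptide", "rpkm_once")) {
  load_unit <- match.arg(load_unit)
  weighted_mode <- match.arg(weighted_mode)
  passing <- quant[quant$passes_filters %in% TRUE, , drop = FALSE]
  binders <- calls[calls$is_binder, , drop = FALSE]
  n_events <- length(unique(genomic_key_of(passing$event_id)))
  if (!nrow(binders))
    return(data.frame(sample_id = sample_id, n_events = n_events,
                      neoag_load = 0L, weighted_load = 0))
  src <- peptides[peptides$peptide %in% binders$peptide, , drop = FALSE]
  orphans <- setdiff(binders$peptide, src$peptide)
  if (length(orphans))
    stop("binder peptide(s) with no source event: ",
         paste(utils::head(orphans, 3), collapse = ", "))
  if (!all(src$event_id %in% passing$event_id))
    stop("binder peptide traces to an event absent from passing quant records")
  load <- if (load_unit == "peptide") length(unique(binders$peptide)) else
    nrow(unique(binders[binders$is_binder, c("peptide", "allele")]))
  rpkm <- setNames(passing$intron_rpkm, passing$event_id)
  per_event <- tapply(src$peptide, src$event_id,
                      function(p) length(unique(p)))
  w <- if (weighted_mode == "per_peptide")
    sum(rpkm[names(per_event)] * as.numeric(per_event))
  else sum(rpkm[names(per_event)])
  data.frame(sample_id = sample_id, n_events = n_events,
             neoag_load = as.integer(load), weighted_load = as.numeric(w))
}

#' Cohort-level allele presentation summary
#'
#' @param calls_by_sample named list (sample_id -> binding calls data.frame)
#' @param genotypes long data.frame: sample_id, allele
#' @return data.frame per allele: allele, carrier_frequency,
#'   n_presented_peptides (unique binder peptides across carrier samples)
#' @export
cohort_allele_summary <- function(calls_by_sample, genotypes) {
  genotypes$allele <- normalize_hla(genotypes$allele)
  samples <- unique(genotypes$sample_id)
  miss <- setdiff(names(calls_by_sample), samples)
  if (length(miss)) stop("genotypes missing for sample(s): ",
                         paste(miss, collapse = ", "))
  alleles <- sort(unique(genotypes$allele))
  rows <- lapply(alleles, function(a) {
    carriers <- unique(genotypes$sample_id[genotypes$allele == a])
    peps <- unlist(lapply(intersect(carriers, names(calls_by_sample)),
                          function(s) {
      cc <- calls_by_sample[[s]]
      cc$peptide[cc$is_binder & cc$allele == a]
    }), use.names = FALSE)
    data.frame(allele = a,
               carrier_frequency = length(carriers) / length(samples),
               n_presented_peptides = length(unique(peps)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shared-peptide frequency across a cohort
#'
#' @param per_sample_binders list of per-sample binder peptide vectors
#' @param threshold sharing threshold on the sample fraction (strict >,
#'   default 0.05)
#' @return data.frame: peptide, sample_fraction, shared_flag
#' @export
shared_peptide_frequency <- function(per_sample_binders, threshold = 0.05) {
  stopifnot(length(per_sample_binders) >= 1L)
  n <- length(per_sample_binders)
  sets <- lapply(per_sample_binders, unique)
  tab <- table(unlist(sets, use.names = FALSE))
  frac <- as.numeric(tab) / n
  data.frame(peptide = names(tab), sample_fraction = frac,
             shared_flag = frac > threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}
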