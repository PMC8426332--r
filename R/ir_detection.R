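#' Intron retention detection
#'
#' Region-level quantification of introns and their flanking exons, the two
#' retention filters (strict count > 10 on all three regions; strict TPM
#' ratio between 0.05 and 0.5), and normal-panel subtraction.
#'
#' @name ir_detection
NULL

#' Filter configuration for IR event calling
#'
#' Thresholds are strict inequalities, read literally: a region passes the
#' depth clause only when its count exceeds `min_region_count`, and the
#' intron/flank TPM ratio must lie strictly between `ratio_low` and
#' `ratio_high`.
#'
#' @param min_region_count exclusive lower bound on intron and both flanking
#'   exon read counts (default 10)
#' @param ratio_low,ratio_high exclusive bounds on intron/flank TPM ratio
#'   (defaults 0.05 and 0.5)
#' @param flank_agg how the two flanking-exon TPMs are aggregated: "mean"
#'   (default) or "min"
#' @param mapq_unique minimum MAPQ treated as uniquely mapped when no NH tag
#'   is present (255 = STAR's unique-mapper convention)
#' @return a `filter_config` list
#' @export
filter_config <- function(min_region_count = 10, ratio_low = 0.05,
                          ratio_high = 0.5, flank_agg = c("mean", "min"),
                          mapq_unique = 255L) {
  flank_agg <- match.arg(flank_agg)
  stopifnot(ratio_low >= 0, ratio_low < ratio_high, min_region_count >= 0)
  structure(list(min_region_count = min_region_count, ratio_low = ratio_low,
                 ratio_high = ratio_high, flank_agg = flank_agg,
                 mapq_unique = as.integer(mapq_unique)),
            class = "filter_config")
}

# Unique regions (introns + flanking exons) of an intron model table.
# An exon flanking two introns appears once; region ids are coordinate keys.
region_universe <- function(introns) {
  reg <- function(start, end, role) {
    data.frame(event_id = introns$event_id, role = role,
               region_id = paste0(introns$chrom, ":", start, "-", end),
               length = end - start, stringsAsFactors = FALSE)
  }
  rbind(reg(introns$intron_start, introns$intron_end, "intron"),
        reg(introns$up_start, introns$up_end, "up"),
        reg(introns$down_start, introns$down_end, "down"))
}

#' Count uniquely mapped reads over introns and flanking exons
#'
#' A read contributes to a region when any of its aligned blocks (CIGAR
#' M/=/X segments) overlaps the region by at least 1 bp; a spliced read
#' whose N gap spans an intron therefore never counts toward that intron.
#' Uniqueness requires `NH == 1` when the NH tag is present, otherwise
#' `MAPQ >= mapq_unique`. `library_size` is the number of distinct unique
#' reads that touch any region of the universe.
#'
#' @param bam_path coordinate-sorted, indexed BAM
#' @param introns intron model data.frame (see [extract_introns()])
#' @param mapq_unique MAPQ threshold for uniqueness without an NH tag
#' @return data.frame: event_id, intron_count, up_count, down_count,
#'   library_size
#' @export
count_regions <- function(bam_path, introns, mapq_unique = 255L) {
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  missing <- setdiff(unique(introns$chrom), names(hdr))
  if (length(missing))
    stop("contig(s) in annotation absent from BAM header: ",
         paste(missing, collapse = ", "))
  param <- Rsamtools::ScanBamParam(
    what = "mapq", tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam_path, param = param)
  nh <- S4Vectors::mcols(gal)$NH
  mapq <- S4Vectors::mcols(gal)$mapq
  uniq <- if (is.null(nh)) mapq >= mapq_unique else
    ifelse(is.na(nh), mapq >= mapq_unique, nh == 1L)
  gal <- gal[uniq]
  uni <- region_universe(introns)
  regions <- unique(uni[, c("region_id", "length")])
  coords <- parse_region_id(regions$region_id)
  reg_gr <- GenomicRanges::GRanges(
    coords$chrom, IRanges::IRanges(coords$start + 1L, coords$end))
  blocks <- GenomicAlignments::grglist(gal)  # aligned blocks per read
  hits <- GenomicAlignments::findOverlaps(blocks, reg_gr, minoverlap = 1L)
  pair <- unique(cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)))
  reg_counts <- setNames(rep(0L, nrow(regions)), regions$region_id)
  if (nrow(pair)) {
    tab <- table(factor(pair[, 2], levels = seq_len(nrow(regions))))
    reg_counts[] <- as.integer(tab)
  }
  lib <- length(unique(pair[, 1]))
  assemble_region_counts(introns, reg_counts, lib)
}

parse_region_id <- function(region_id) {
  m <- regmatches(region_id, regexec("^(.*):(\\d+)-(\\d+)$", region_id))
  data.frame(chrom = vapply(m, `[[`, "", 2L),
             start = as.integer(vapply(m, `[[`, "", 3L)),
             end = as.integer(vapply(m, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

assemble_region_counts <- function(introns, reg_counts, library_size) {
  id <- function(s, e) paste0(introns$chrom, ":", s, "-", e)
  data.frame(
    event_id = introns$event_id,
    intron_count = unname(reg_counts[id(introns$intron_start, introns$intron_end)]),
    up_count = unname(reg_counts[id(introns$up_start, introns$up_end)]),
    down_count = unname(reg_counts[id(introns$down_start, introns$down_end)]),
    library_size = library_size, stringsAsFactors = FALSE)
}

#' Read a per-sample region count table
#'
#' Bypass for BAM counting: a TSV with columns sample_id (optional),
#' event_id, intron_count, up_count, down_count, library_size.
#' @param path TSV path
#' @return data.frame of region counts
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  need <- c("event_id", "intron_count", "up_count", "down_count",
            "library_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Region-level TPM/RPKM quantification for one sample
#'
#' TPM is computed over the universe of all intron and flanking-exon regions
#' of the annotation: `rate_r = count_r / length_r`, `TPM_r = rate_r /
#' sum(rates) * 1e6`. Regions shared between events (an exon flanking two
#' introns) enter the denominator once. `flank_tpm` aggregates the two
#' flanking-exon TPMs per `cfg$flank_agg`; `tpm_ratio` is undefined (NA)
#' when `flank_tpm` is 0. `intron_rpkm = count / (length_kb *
#' library_size/1e6)`.
#'
#' @param counts region counts for one sample (see [count_regions()])
#' @param introns intron model data.frame supplying region coordinates and
#'   lengths
#' @param cfg a [filter_config()]
#' @return IR quantification data.frame: event_id, counts, intron_tpm,
#'   flank_tpm, tpm_ratio, intron_rpkm, passes_filters (NA until
#'   [apply_ir_filters()])
#' @export
compute_region_tpm <- function(counts, introns, cfg = filter_config()) {
  introns <- introns[match(counts$event_id, introns$event_id), , drop = FALSE]
  if (anyNA(introns$event_id))
    stop("count table contains event_id(s) absent from intron models")
  id <- function(s, e) paste0(introns$chrom, ":", s, "-", e)
  long <- data.frame(
    region_id = c(id(introns$intron_start, introns$intron_end),
                  id(introns$up_start, introns$up_end),
                  id(introns$down_start, introns$down_end)),
    length = c(introns$intron_end - introns$intron_start,
               introns$up_end - introns$up_start,
               introns$down_end - introns$down_start),
    count = c(counts$intron_count, counts$up_count, counts$down_count))
  uniq <- long[!duplicated(long$region_id), , drop = FALSE]
  stopifnot(all(uniq$length > 0))
  rate <- uniq$count / uniq$length
  total <- sum(rate)
  tpm <- if (total > 0) rate / total * 1e6 else rep(NA_real_, length(rate))
  tpm_of <- setNames(tpm, uniq$region_id)
  intron_tpm <- unname(tpm_of[long$region_id[seq_len(nrow(introns))]])
  up_tpm <- unname(tpm_of[id(introns$up_start, introns$up_end)])
  down_tpm <- unname(tpm_of[id(introns$down_start, introns$down_end)])
  flank_tpm <- if (cfg$flank_agg == "mean") (up_tpm + down_tpm) / 2 else
    pmin(up_tpm, down_tpm)
  ratio <- ifelse(!is.na(flank_tpm) & flank_tpm > 0,
                  intron_tpm / flank_tpm, NA_real_)
  ilen <- introns$intron_end - introns$intron_start
  rpkm <- ifelse(counts$library_size > 0,
                 counts$intron_count / (ilen / 1e3 * counts$library_size / 1e6),
                 NA_real_)
  data.frame(event_id = counts$event_id,
             intron_count = counts$intron_count,
             up_count = counts$up_count, down_count = counts$down_count,
             library_size = counts$library_size,
             intron_tpm = intron_tpm, flank_tpm = flank_tpm,
             tpm_ratio = ratio, intron_rpkm = rpkm,
             passes_filters = NA, stringsAsFactors = FALSE)
}

#' Apply the IR retention filters
#'
#' An event passes iff intron, upstream-exon, and downstream-exon counts all
#' strictly exceed `cfg$min_region_count` AND the TPM ratio lies strictly
#' inside (`cfg$ratio_low`, `cfg$ratio_high`). An undefined ratio fails.
#'
#' @param quant quantification data.frame from [compute_region_tpm()]
#' @param cfg a [filter_config()]
#' @return `quant` with `passes_filters` filled in
#' @export
apply_ir_filters <- function(quant, cfg = filter_config()) {
  ok_counts <- quant$intron_count > cfg$min_region_count &
    quant$up_count > cfg$min_region_count &
    quant$down_count > cfg$min_region_count
  ok_ratio <- !is.na(quant$tpm_ratio) &
    quant$tpm_ratio > cfg$ratio_low & quant$tpm_ratio < cfg$ratio_high
  quant$passes_filters <- ok_counts & ok_ratio
  quant
}

#' Events called in one sample
#'
#' @param quant filtered quantification data.frame
#' @param dedupe collapse events sharing a genomic interval (default TRUE;
#'   the first transcript's event_id represents the interval)
#' @return character vector of passing event_ids
#' @export
call_sample_events <- function(quant, dedupe = TRUE) {
  ids <- quant$event_id[quant$passes_filters %in% TRUE]
  if (dedupe && length(ids)) ids <- ids[!duplicated(genomic_key_of(ids))]
  ids
}

#' Build the normal-sample event panel
#'
#' Union over normal samples of their passing event sets: presence in at
#' least one normal sample puts an event on the panel (no frequency
#' threshold). Normals must be quantified with the same [filter_config()] as
#' tumors.
#'
#' @param normal_events list of per-normal event_id vectors (or of filtered
#'   quantification data.frames)
#' @return character vector of panel event_ids
#' @export
build_normal_panel <- function(normal_events) {
  if (!length(normal_events)) {
    warning("empty normal panel: no normal samples provided")
    return(character(0))
  }
  sets <- lapply(normal_events, function(x)
    if (is.data.frame(x)) call_sample_events(x) else x)
  ids <- unique(unlist(sets, use.names = FALSE))
  if (is.null(ids)) character(0) else ids
}

#' Subtract the normal panel from a tumor event set
#'
#' Comparison is by genomic interval (chrom:start-end:strand), so the same
#' intron reached through different transcripts in tumor and normal is still
#' subtracted.
#'
#' @param tumor_events,panel character vectors of event_ids
#' @return tumor event_ids not present in the panel
#' @export
subtract_normal <- function(tumor_events, panel) {
  if (!length(tumor_events)) return(character(0))
  if (!length(panel)) return(tumor_events)
  tumor_events[!genomic_key_of(tumor_events) %in% genomic_key_of(panel)]
}

#' Quantify and filter a multi-sample count table
#'
#' Convenience wrapper: splits a long count table by sample, computes
#' region TPM/RPKM, and applies the filters.
#'
#' @param counts long data.frame with a sample_id column plus the
#'   [read_count_table()] columns
#' @param introns intron model data.frame
#' @param cfg a [filter_config()]
#' @return data.frame of per-sample quantification records with
#'   `passes_filters` and a `sample_id` column
#' @export
quantify_cohort <- function(counts, introns, cfg = filter_config()) {
  stopifnot("sample_id" %in% names(counts))
  out <- lapply(split(counts, counts$sample_id), function(sub) {
    q <- apply_ir_filters(compute_region_tpm(sub, introns, cfg), cfg)
    q$sample_id <- sub$sample_id[1]
    q
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
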