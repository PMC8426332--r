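#' Synthetic study generator
#'
#' Builds a fully self-contained study: a toy genome and annotation with
#' known CDS frames, a proteome derived from the annotated CDS (so
#' intron-derived peptides are non-self by construction, except for planted
#' self-decoys), per-sample region counts with planted IR events whose TPM
#' ratios fall inside the retention window, decoy events violating exactly
#' one filter clause, a disjoint normal-panel event set, HLA genotypes, and
#' survival outcomes whose hazard depends on neoantigen load. Everything is
#' deterministic given the seed.
#'
#' @name synthetic_data
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults define the package's reference study: 20 genes of 4 exons,
#' 50 tumor and 5 normal samples, negative-binomial exon coverage with mean
#' 300 reads and mild overdispersion, planted retention ratios well inside
#' the (0.05, 0.5) window, a 6-event normal panel, 12-allele HLA pool with
#' 6 alleles per sample, and a 2-fold hazard for high neoantigen load with
#' roughly 30% censoring.
#'
#' @param seed master seed; every derived stream is seeded from it
#' @param n_genes,exons_per_gene gene structure
#' @param exon_length_range,intron_length_range bp ranges (intron lengths
#'   are overridden per decoy class so each decoy can violate exactly one
#'   filter clause)
#' @param n_tumor_samples,n_normal_samples cohort sizes
#' @param planted_event_fraction fraction of introns planted as
#'   tumor-specific retained events
#' @param n_panel_events events planted in normal samples (and tumors) that
#'   the panel must remove
#' @param n_decoys_per_class decoys per class (count boundary, ratio high,
#'   ratio low)
#' @param planted_ratio_range retention TPM-ratio range for planted events
#' @param decoy_ratio_high,decoy_ratio_low target ratios outside the window
#' @param base_depth mean reads per exon region
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2)
#' @param retention_prob_range per-tumor-sample probability range of
#'   retaining each planted event (drives load variation across samples)
#' @param allele_pool HLA class I allele pool
#' @param alleles_per_sample alleles drawn per sample (2 per locus)
#' @param true_log_hr planted log hazard ratio of high vs low load
#' @param baseline_hazard exponential baseline hazard per month
#' @param censoring_rate target fraction of censored samples
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = 4L,
                       exon_length_range = c(150L, 300L),
                       intron_length_range = c(300L, 600L),
                       n_tumor_samples = 50L, n_normal_samples = 5L,
                       planted_event_fraction = 0.25,
                       n_panel_events = 6L, n_decoys_per_class = 3L,
                       planted_ratio_range = c(0.1, 0.4),
                       decoy_ratio_high = 0.7, decoy_ratio_low = 0.02,
                       base_depth = 300, nb_dispersion = 0.02,
                       retention_prob_range = c(0.3, 0.9),
                       allele_pool = c(
                         "HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01",
                         "HLA-A*24:02", "HLA-B*07:02", "HLA-B*08:01",
                         "HLA-B*35:01", "HLA-B*44:02", "HLA-C*04:01",
                         "HLA-C*05:01", "HLA-C*07:01", "HLA-C*07:02"),
                       alleles_per_sample = 6L,
                       true_log_hr = log(2), baseline_hazard = log(2) / 40,
                       censoring_rate = 0.3) {
  stopifnot(planted_ratio_range[1] > 0.05, planted_ratio_range[2] < 0.5,
            n_genes >= 1, exons_per_gene >= 2, n_tumor_samples >= 2,
            alleles_per_sample %% 2 == 0)
  structure(as.list(environment()), class = "sim_config")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

random_codons <- function(n_codons, exclude_stop = TRUE) {
  if (n_codons == 0L) return("")
  pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  if (exclude_stop) pool <- setdiff(pool, STOP_CODONS)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

#' Build the synthetic reference (genome, annotation, proteome)
#'
#' Each gene sits on its own contig with 100 bp flanks; strands alternate.
#' The CDS spans every exon completely and contains no in-frame stop, so
#' the junction frame at intron i is the cumulative exon length mod 3.
#' Intron roles are assigned up front (planted tumor-specific, normal-panel,
#' three decoy classes, background) and drive intron lengths; planted
#' introns carry a long open reading frame (no stop for 5-12 codons)
#' except for a few immediate-stop introns planted at frame-0 junctions.
#' The proteome holds every translated CDS plus planted self-decoy entries:
#' junction 9-mers of some planted events that [filter_self()] must remove.
#'
#' @param cfg a [sim_config()]
#' @param out_dir directory for genome.fa, annotation.gtf, proteome.fa
#' @return list: paths, genes (gene_model list), introns (model table with
#'   a `role` column), decoy_self_peptides
#' @export
make_reference <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, {
    n_introns_per_gene <- cfg$exons_per_gene - 1L
    n_total <- cfg$n_genes * n_introns_per_gene
    roles <- rep("background", n_total)
    n_planted <- max(1L, round(cfg$planted_event_fraction * n_total))
    pool <- sample(n_total)
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    roles[take(n_planted)] <- "planted"
    roles[take(min(cfg$n_panel_events, length(pool)))] <- "panel"
    for (cl in c("count_decoy", "ratio_high_decoy", "ratio_low_decoy"))
      roles[take(min(cfg$n_decoys_per_class, length(pool)))] <- cl
    genes <- vector("list", cfg$n_genes)
    intron_rows <- list()
    ridx <- 0L
    for (g in seq_len(cfg$n_genes)) {
      strand <- if (g %% 2L == 1L) "+" else "-"
      chrom <- sprintf("chrS%02d", g)
      n_ex <- cfg$exons_per_gene
      ex_len <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                       n_ex, replace = TRUE)
      # total CDS length divisible by 3 for a clean proteome translation
      ex_len[n_ex] <- ex_len[n_ex] + (3L - sum(ex_len) %% 3L) %% 3L
      gene_roles <- roles[ridx + seq_len(n_ex - 1L)]
      ridx <- ridx + n_ex - 1L
      in_len <- vapply(gene_roles, function(r) switch(
        r,
        count_decoy = sample(45:60, 1),
        ratio_low_decoy = sample(900:1500, 1),
        sample(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]), 1)
      ), 0L)
      cds_nt <- paste0("ATG", random_codons(sum(ex_len) / 3L - 1L))
      cum <- cumsum(ex_len)
      exon_seqs <- substring(cds_nt, c(1L, cum[-n_ex] + 1L), cum)
      frames <- cum[-n_ex] %% 3L
      intron_seqs <- character(n_ex - 1L)
      for (i in seq_len(n_ex - 1L)) {
        r <- frames[i]
        partial <- if (r > 0L) substring(exon_seqs[i], ex_len[i] - r + 1L,
                                         ex_len[i]) else ""
        comp_len <- (3L - r) %% 3L
        repeat {
          comp <- if (comp_len > 0L) random_nt(comp_len) else ""
          if (r == 0L || !(paste0(partial, comp) %in% STOP_CODONS)) break
        }
        body_codons <- if (gene_roles[i] %in% c("planted", "panel")) {
          paste0(random_codons(sample(5:12, 1)), "TAA")
        } else random_codons(2L, exclude_stop = FALSE)
        head_nt <- paste0(comp, body_codons)
        stopifnot(nchar(head_nt) < in_len[i])
        intron_seqs[i] <- paste0(head_nt, random_nt(in_len[i] - nchar(head_nt)))
      }
      # lay out on the contig: 100 bp flanks; transcription-order segments
      segs <- character(2L * n_ex - 1L)
      segs[seq(1L, 2L * n_ex - 1L, 2L)] <- exon_seqs
      segs[seq(2L, 2L * n_ex - 2L, 2L)] <- intron_seqs
      tx_seq <- paste(segs, collapse = "")
      L <- nchar(tx_seq)
      genomic_body <- if (strand == "+") tx_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))
      contig_seq <- paste0(random_nt(100L), genomic_body, random_nt(100L))
      seg_len <- nchar(segs)
      seg_end <- cumsum(seg_len); seg_start <- seg_end - seg_len  # tx coords
      to_genomic <- function(s, e) {
        if (strand == "+") c(100L + s, 100L + e) else c(100L + L - e, 100L + L - s)
      }
      ex_idx <- seq(1L, 2L * n_ex - 1L, 2L)
      ex_iv <- t(vapply(ex_idx, function(i)
        to_genomic(seg_start[i], seg_end[i]), c(0, 0)))
      exons <- cbind(start = as.integer(ex_iv[, 1]), end = as.integer(ex_iv[, 2]))
      gm <- structure(list(gene_id = sprintf("G%02d", g),
                           transcript_id = sprintf("G%02d.t1", g),
                           chrom = chrom, strand = strand,
                           exons = exons, cds = exons), class = "gene_model")
      genes[[g]] <- list(model = gm, contig_seq = contig_seq,
                         roles = gene_roles)
    }
    genome <- Biostrings::DNAStringSet(vapply(genes, function(g)
      g$contig_seq, ""))
    names(genome) <- vapply(genes, function(g) g$model$chrom, "")
    genome_path <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, genome_path, width = 80L)
    models <- lapply(genes, `[[`, "model")
    gtf_path <- file.path(out_dir, "annotation.gtf")
    write_gtf(models, gtf_path)
    introns <- extract_all_introns(models)
    introns$role <- unlist(lapply(genes, `[[`, "roles"), use.names = FALSE)
    # proteome: translated CDS of every transcript
    prot <- vapply(models, function(m) {
      nt <- paste(vapply(seq_len(nrow(m$exons)), function(i)
        region_seq(genome, m$chrom, m$exons[i, "start"], m$exons[i, "end"],
                   m$strand), ""), collapse = "")
      translate_codons(nt, stop_at_stop = FALSE)$aa
    }, "")
    names(prot) <- vapply(models, `[[`, "", "transcript_id")
    # planted self-decoys: junction 9-mers from a few planted events
    planted <- introns[introns$role == "planted" & !is.na(introns$frame), ,
                       drop = FALSE]
    n_decoy_self <- min(3L, nrow(planted))
    decoy_peps <- character(0)
    if (n_decoy_self > 0L) for (i in seq_len(n_decoy_self)) {
      tr <- translate_extension(planted[i, ], genome)
      pep <- enumerate_peptides(tr, k_range = 9L)
      if (nrow(pep)) decoy_peps <- c(decoy_peps, pep$peptide[1])
    }
    decoy_peps <- unique(decoy_peps)
    if (length(decoy_peps))
      prot <- c(prot, setNames(decoy_peps,
                               paste0("DECOY_SELF_", seq_along(decoy_peps))))
    proteome_path <- file.path(out_dir, "proteome.fa")
    writeLines(paste0(">", names(prot), "\n", unname(prot)), proteome_path)
    list(genome_path = genome_path, gtf_path = gtf_path,
         proteome_path = proteome_path, genes = models, introns = introns,
         decoy_self_peptides = decoy_peps)
  })
}

#' Simulate per-sample region counts with planted events
#'
#' Exon-region counts are negative binomial around `base_depth`. Planted
#' events (in the samples that retain them) receive intron counts matching
#' a target TPM ratio drawn from `planted_ratio_range`, computed against
#' the realized flank coverage; decoys violate exactly one clause (intron
#' count pinned at the threshold with an in-window ratio, or an out-of-
#' window ratio with counts above threshold); all remaining introns get
#' sub-threshold counts. Normal samples retain only the panel events.
#'
#' @param cfg a [sim_config()]
#' @param introns intron table from [make_reference()] (with `role`)
#' @param out_dir directory for counts.tsv
#' @return list: counts (long data.frame), truth (planted/panel event ids,
#'   per-sample retained sets), counts_path
#' @export
make_counts <- function(cfg, introns, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed + 1L, {
    uni <- region_universe(introns)
    regions <- unique(uni[, c("region_id", "length")])
    exon_regions <- unique(uni$region_id[uni$role != "intron"])
    planted_ids <- introns$event_id[introns$role == "planted"]
    panel_ids <- introns$event_id[introns$role == "panel"]
    samples <- c(sprintf("tumor%02d", seq_len(cfg$n_tumor_samples)),
                 sprintf("normal%02d", seq_len(cfg$n_normal_samples)))
    is_normal <- grepl("^normal", samples)
    ret_prob <- runif(length(samples), cfg$retention_prob_range[1],
                      cfg$retention_prob_range[2])
    retained <- lapply(seq_along(samples), function(i) {
      cand <- if (is_normal[i]) panel_ids else c(planted_ids, panel_ids)
      cand[runif(length(cand)) < ret_prob[i]]
    })
    names(retained) <- samples
    # coverage guarantees: every planted event in >= 1 tumor, every panel
    # event in >= 1 normal
    tum_idx <- which(!is_normal); norm_idx <- which(is_normal)
    for (e in planted_ids)
      if (!any(vapply(retained[tum_idx], function(s) e %in% s, TRUE))) {
        i <- sample(tum_idx, 1)
        retained[[i]] <- c(retained[[i]], e)
      }
    for (e in panel_ids)
      if (!any(vapply(retained[norm_idx], function(s) e %in% s, TRUE))) {
        i <- if (length(norm_idx) > 1) sample(norm_idx, 1) else norm_idx
        retained[[i]] <- c(retained[[i]], e)
      }
    size <- 1 / cfg$nb_dispersion
    ilen <- setNames(introns$intron_end - introns$intron_start,
                     introns$event_id)
    rows <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      reg_counts <- setNames(integer(nrow(regions)), regions$region_id)
      nexon <- length(exon_regions)
      reg_counts[exon_regions] <- rnbinom(nexon, size = size,
                                          mu = cfg$base_depth)
      # guard the depth clause for flanks (astronomically rare at defaults)
      reg_counts[exon_regions] <- pmax(reg_counts[exon_regions], 12L)
      flank_rate <- function(ev) {
        r <- introns[introns$event_id == ev, ]
        up_id <- paste0(r$chrom, ":", r$up_start, "-", r$up_end)
        dn_id <- paste0(r$chrom, ":", r$down_start, "-", r$down_end)
        mean(c(reg_counts[up_id] / (r$up_end - r$up_start),
               reg_counts[dn_id] / (r$down_end - r$down_start)))
      }
      for (j in seq_len(nrow(introns))) {
        ev <- introns$event_id[j]
        role <- introns$role[j]
        iid <- paste0(introns$chrom[j], ":", introns$intron_start[j], "-",
                      introns$intron_end[j])
        target_count <- function(ratio)
          max(1L, as.integer(round(ratio * flank_rate(ev) * ilen[ev])))
        reg_counts[iid] <-
          if (ev %in% retained[[i]]) {
            # floor at 12 keeps the depth clause satisfied even under a deep
            # coverage draw; the implied ratio stays inside the window
            max(12L, target_count(runif(1, cfg$planted_ratio_range[1],
                                        cfg$planted_ratio_range[2])))
          } else if (role == "count_decoy" && !is_normal[i]) {
            10L
          } else if (role == "ratio_high_decoy" && !is_normal[i]) {
            target_count(cfg$decoy_ratio_high)
          } else if (role == "ratio_low_decoy" && !is_normal[i]) {
            target_count(cfg$decoy_ratio_low)
          } else {
            sample(0:9, 1)
          }
      }
      lib <- sum(reg_counts)
      rc <- assemble_region_counts(introns, reg_counts, lib)
      rc$sample_id <- samples[i]
      rows[[i]] <- rc
    }
    counts <- do.call(rbind, rows)
    counts <- counts[, c("sample_id", "event_id", "intron_count", "up_count",
                         "down_count", "library_size")]
    counts_path <- file.path(out_dir, "counts.tsv")
    write_tsv(counts, counts_path)
    list(counts = counts, counts_path = counts_path,
         truth = list(planted_tumor = planted_ids, panel = panel_ids,
                      retained_by_sample = retained))
  })
}

#' Simulate HLA genotypes
#'
#' Two alleles per locus per sample, drawn with replacement from the pool.
#' @param cfg a [sim_config()]
#' @param sample_ids samples to genotype
#' @param out_dir directory for genotypes.tsv
#' @return list: genotypes (long data.frame sample_id/allele),
#'   genotypes_path
#' @export
make_genotypes <- function(cfg, sample_ids, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed + 2L, {
    locus <- sub("^HLA-([A-Z]+).*$", "\\1", cfg$allele_pool)
    per_locus <- split(cfg$allele_pool, locus)
    rows <- lapply(sample_ids, function(s) {
      alle <- unlist(lapply(per_locus, function(p)
        sample(p, cfg$alleles_per_sample / length(per_locus),
               replace = TRUE)), use.names = FALSE)
      data.frame(sample_id = s, allele = alle, stringsAsFactors = FALSE)
    })
    genotypes <- do.call(rbind, rows)
    genotypes_path <- file.path(out_dir, "genotypes.tsv")
    write_tsv(genotypes, genotypes_path)
    list(genotypes = genotypes, genotypes_path = genotypes_path)
  })
}

#' Simulate clinical outcomes with a planted load-hazard association
#'
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(true_log_hr * I(load > median))`; censoring times
#' are independent exponentials whose rate targets `censoring_rate`
#' censored samples; age and sex are generated independently of load.
#'
#' @param cfg a [sim_config()]
#' @param loads per-sample load data.frame (see [compute_sample_load()])
#' @param out_dir directory for clinical.tsv
#' @param load_field which load drives the hazard
#' @return list: clinical (data.frame sample_id, time, event, age, sex),
#'   clinical_path
#' @export
make_cohort <- function(cfg, loads, out_dir,
                        load_field = "neoag_load") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed + 3L, {
    v <- loads[[load_field]]
    high <- v > median(v)
    n <- nrow(loads)
    hz <- cfg$baseline_hazard * exp(cfg$true_log_hr * high)
    t_event <- rexp(n, rate = hz)
    if (cfg$censoring_rate > 0) {
      c_rate <- cfg$baseline_hazard * cfg$censoring_rate /
        (1 - cfg$censoring_rate)
      t_cens <- rexp(n, rate = c_rate)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n); time <- t_event
    }
    clinical <- data.frame(
      sample_id = loads$sample_id, time = round(time, 3), event = event,
      age = round(stats::rnorm(n, 65, 8)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    clinical_path <- file.path(out_dir, "clinical.tsv")
    write_tsv(clinical, clinical_path)
    list(clinical = clinical, clinical_path = clinical_path)
  })
}
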