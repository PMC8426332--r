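#' Pipeline orchestration
#'
#' One reproducible run: detect IR events per tumor sample, subtract the
#' normal panel, translate and enumerate candidate peptides, remove
#' self-peptides, call binders against each patient's HLA genotype, compute
#' loads, and (when a clinical table is supplied) run the outcome
#' statistics. A manifest records inputs, parameters, a parameter hash, and
#' per-stage row counts.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' @param gtf,genome,proteome,counts,genotypes input paths; `clinical` is
#'   optional (outcome statistics are skipped without it)
#' @param normal_samples sample_ids in the count table forming the normal
#'   panel; all other samples are treated as tumors
#' @param predictor predictor spec: `"surrogate:<seed>"` or
#'   `"netmhcpan-file:<path>"`
#' @param filter a [filter_config()]
#' @param rank_cutoff binder threshold (strict <)
#' @param load_unit,weighted_mode see [compute_sample_load()]
#' @param load_field load used for dichotomization and the planted hazard
#' @param covariates clinical covariate columns for the multivariate Cox
#'   fit (the load group is always included)
#' @param out_dir output directory
#' @param clinical optional clinical TSV path
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(gtf, genome, proteome, counts, genotypes,
                            normal_samples, predictor = "surrogate:0",
                            filter = filter_config(), rank_cutoff = 2.0,
                            load_unit = "peptide",
                            weighted_mode = "per_peptide",
                            load_field = "neoag_load",
                            covariates = c("age", "sex"),
                            out_dir = "neoir_out", clinical = NULL) {
  cfg <- list(gtf = gtf, genome = genome, proteome = proteome,
              counts = counts, genotypes = genotypes,
              clinical = clinical, normal_samples = normal_samples,
              predictor = predictor, filter = filter,
              rank_cutoff = rank_cutoff, load_unit = load_unit,
              weighted_mode = weighted_mode, load_field = load_field,
              covariates = covariates, out_dir = out_dir)
  paths <- c(gtf, genome, proteome, counts, genotypes, clinical)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("pipeline input path(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; filter
#' thresholds may be given under a `filter:` block (min_region_count,
#' ratio_low, ratio_high, flank_agg, mapq_unique).
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fil <- do.call(filter_config, y$filter %||% list())
  y$filter <- NULL
  base <- dirname(normalizePath(path))
  for (f in c("gtf", "genome", "proteome", "counts", "genotypes", "clinical"))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  do.call(pipeline_config, c(y, list(filter = fil)))
}

parse_predictor <- function(spec) {
  parts <- regmatches(spec, regexec("^([a-z-]+):(.*)$", spec))[[1]]
  if (length(parts) != 3L)
    stop("predictor spec must be 'surrogate:<seed>' or 'netmhcpan-file:<path>'")
  switch(parts[2],
         "surrogate" = surrogate_predictor(as.integer(parts[3])),
         "netmhcpan-file" = netmhcpan_file_predictor(parts[3]),
         stop("unknown predictor type: ", parts[2]))
}

stage_log <- function(stage, n, detail = "") {
  message(sprintf("[neoIR] %-18s rows=%-8d %s", stage, n, detail))
}

#' Run the full IR-neoantigen pipeline
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) a list with per-stage results and the manifest;
#'   writes events, peptide, binding, load and statistics tables plus
#'   manifest.json under `cfg$out_dir`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts_stage <- list()

  genes <- load_annotation(cfg$gtf, cfg$genome)
  genome <- read_genome(cfg$genome)
  introns <- extract_all_introns(genes)
  stage_log("annotation", nrow(introns), paste0(length(genes), " transcripts"))
  counts_stage$introns <- nrow(introns)

  counts <- read_count_table(cfg$counts)
  if (!"sample_id" %in% names(counts))
    stop("count table must contain a sample_id column for cohort runs")
  quant <- quantify_cohort(counts, introns, cfg$filter)
  counts_stage$quant_records <- nrow(quant)
  is_normal <- quant$sample_id %in% cfg$normal_samples
  tumor_ids <- unique(quant$sample_id[!is_normal])
  if (!length(tumor_ids)) stop("no tumor samples in count table")

  by_sample <- split(quant, quant$sample_id)
  tumor_events <- lapply(by_sample[tumor_ids], call_sample_events)
  panel <- build_normal_panel(
    by_sample[intersect(cfg$normal_samples, names(by_sample))])
  specific <- lapply(tumor_events, subtract_normal, panel = panel)
  stage_log("ir_detection", sum(lengths(tumor_events)),
            paste0("panel=", length(panel)))
  stage_log("subtract_normal", sum(lengths(specific)))
  counts_stage$tumor_events <- sum(lengths(tumor_events))
  counts_stage$panel_events <- length(panel)
  counts_stage$specific_events <- sum(lengths(specific))

  all_specific <- unique(unlist(specific, use.names = FALSE))
  ev_tab <- introns[introns$event_id %in% all_specific, , drop = FALSE]
  translations <- translate_all(ev_tab, genome)
  peptides <- enumerate_peptides(translations)
  counts_stage$peptides <- nrow(peptides)
  index <- build_proteome_index(cfg$proteome)
  nonself <- filter_self(peptides, index)
  counts_stage$nonself_peptides <- nrow(nonself)
  stage_log("translate", nrow(translations))
  stage_log("peptides", nrow(peptides),
            paste0("nonself=", nrow(nonself)))

  genotypes <- read_tsv(cfg$genotypes)
  predictor <- parse_predictor(cfg$predictor)
  calls_by_sample <- list(); loads <- list()
  for (s in tumor_ids) {
    ev <- specific[[s]]
    pep_s <- nonself[nonself$event_id %in% ev, , drop = FALSE]
    alle <- genotypes$allele[genotypes$sample_id == s]
    if (!length(alle)) stop("no HLA genotype for sample ", s)
    calls <- if (nrow(pep_s))
      predict_binding(unique(pep_s$peptide), alle, predictor,
                      cfg$rank_cutoff)
    else data.frame(peptide = character(0), allele = character(0),
                    rank_score = numeric(0), is_binder = logical(0))
    calls_by_sample[[s]] <- calls
    q_s <- by_sample[[s]]
    q_s <- q_s[q_s$event_id %in% ev, , drop = FALSE]
    loads[[s]] <- compute_sample_load(calls, q_s, pep_s, sample_id = s,
                                      load_unit = cfg$load_unit,
                                      weighted_mode = cfg$weighted_mode)
  }
  loads <- do.call(rbind, loads); rownames(loads) <- NULL
  counts_stage$binder_calls <-
    sum(vapply(calls_by_sample, function(x) sum(x$is_binder), 0))
  counts_stage$samples_loaded <- nrow(loads)
  stage_log("binding", counts_stage$binder_calls)
  stage_log("loads", nrow(loads))

  write_tsv(quant, file.path(cfg$out_dir, "ir_quant.tsv"))
  write_tsv(data.frame(sample_id = rep(names(specific), lengths(specific)),
                       event_id = unlist(specific, use.names = FALSE)),
            file.path(cfg$out_dir, "specific_events.tsv"))
  write_tsv(nonself, file.path(cfg$out_dir, "neopeptides.tsv"))
  write_tsv(loads, file.path(cfg$out_dir, "sample_loads.tsv"))

  stats <- NULL
  if (!is.null(cfg$clinical)) {
    clinical <- read_tsv(cfg$clinical)
    stats <- outcome_stats(loads, clinical, load_field = cfg$load_field,
                           covariates = cfg$covariates)
    jsonlite::write_json(stats$summary,
                         file.path(cfg$out_dir, "outcome_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(stats$cox_table, file.path(cfg$out_dir, "cox_table.tsv"))
    stage_log("outcome_stats", nrow(stats$cox_table))
  }

  manifest <- list(
    package = "neoIR",
    version = as.character(utils::packageVersion("neoIR")),
    inputs = cfg[c("gtf", "genome", "proteome", "counts", "genotypes",
                   "clinical")],
    parameters = list(filter = unclass(cfg$filter),
                      predictor = cfg$predictor,
                      rank_cutoff = cfg$rank_cutoff,
                      load_unit = cfg$load_unit,
                      weighted_mode = cfg$weighted_mode),
    parameter_hash = fnv1a32(paste(deparse(
      cfg[c("filter", "predictor", "rank_cutoff", "load_unit",
            "weighted_mode", "load_field", "covariates")]), collapse = "")),
    stage_rows = counts_stage)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(introns = introns, quant = quant, panel = panel,
                 tumor_events = tumor_events, specific_events = specific,
                 translations = translations, peptides = peptides,
                 nonself = nonself, calls_by_sample = calls_by_sample,
                 loads = loads, stats = stats, manifest = manifest))
}

#' Outcome statistics for a load table and clinical table
#'
#' Median-dichotomizes the load, runs the two-group log-rank test, and fits
#' univariate (load group only) and multivariate (load group + covariates)
#' Cox models.
#'
#' @param loads per-sample load data.frame
#' @param clinical data.frame: sample_id, time, event, covariates
#' @param load_field load column to dichotomize
#' @param covariates additional covariate columns for the multivariate fit
#' @return list: records (merged table with load_group), km_by_group,
#'   logrank, cox_uni, cox_multi, cox_table, summary
#' @export
outcome_stats <- function(loads, clinical, load_field = "neoag_load",
                          covariates = c("age", "sex")) {
  grp <- dichotomize_load(loads, load_field)
  rec <- merge(clinical, data.frame(sample_id = names(grp),
                                    load_group = unname(grp)),
               by = "sample_id")
  km <- lapply(split(rec, rec$load_group),
               function(d) km_estimate(d$time, d$event))
  lr <- logrank_test(rec$time, rec$event, rec$load_group)
  cox_uni <- cox_fit(rec, "load_group")
  covariates <- intersect(covariates, names(rec))
  cox_multi <- if (length(covariates))
    cox_fit(rec, c("load_group", covariates)) else NULL
  tab <- cox_uni$coefficients
  tab$model <- "univariate"
  if (!is.null(cox_multi)) {
    t2 <- cox_multi$coefficients
    t2$model <- "multivariate"
    tab <- rbind(tab, t2)
  }
  summary <- list(
    n = nrow(rec), n_events = sum(rec$event),
    n_high = sum(rec$load_group == "high"),
    logrank_chi_square = lr$chi_square, logrank_p = lr$p_value,
    cox_uni_hr = cox_uni$coefficients$hazard_ratio[1],
    cox_uni_p = cox_uni$coefficients$wald_p[1])
  list(records = rec, km_by_group = km, logrank = lr, cox_uni = cox_uni,
       cox_multi = cox_multi, cox_table = tab, summary = summary)
}

#' Simulate a complete study to disk
#'
#' Generates reference, counts, and genotypes; runs the pipeline to obtain
#' loads; simulates clinical outcomes from those loads; and writes a
#' ready-to-run pipeline.yaml beside the data.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory
#' @return (invisibly) list: cfg, reference, counts, genotypes, clinical,
#'   pipeline (the run used to derive loads), paths
#' @export
simulate_study <- function(cfg = sim_config(), out_dir) {
  ref <- make_reference(cfg, out_dir)
  cnt <- make_counts(cfg, ref$introns, out_dir)
  samples <- unique(cnt$counts$sample_id)
  tumor_ids <- samples[!grepl("^normal", samples)]
  gen <- make_genotypes(cfg, tumor_ids, out_dir)
  pcfg <- pipeline_config(
    gtf = ref$gtf_path, genome = ref$genome_path,
    proteome = ref$proteome_path, counts = cnt$counts_path,
    genotypes = gen$genotypes_path,
    normal_samples = samples[grepl("^normal", samples)],
    predictor = paste0("surrogate:", cfg$seed),
    out_dir = file.path(out_dir, "pipeline_out"))
  run <- run_pipeline(pcfg)
  clin <- make_cohort(cfg, run$loads, out_dir)
  yaml::write_yaml(list(
    gtf = "annotation.gtf", genome = "genome.fa", proteome = "proteome.fa",
    counts = "counts.tsv", genotypes = "genotypes.tsv",
    clinical = "clinical.tsv",
    normal_samples = as.list(samples[grepl("^normal", samples)]),
    predictor = paste0("surrogate:", cfg$seed),
    out_dir = file.path(out_dir, "pipeline_out")),
    file.path(out_dir, "pipeline.yaml"))
  invisible(list(cfg = cfg, reference = ref, counts = cnt, genotypes = gen,
                 clinical = clin, pipeline = run,
                 paths = list(out_dir = out_dir)))
}
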