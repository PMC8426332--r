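test_that("ORF extension translates through the junction and stops at stops", {
  # exon CDS ends ...GCTAAG in frame 0; intron begins GGG TGA ...
  d <- designed_gene(exon1 = "ATGGCTAAG",
                     intron = paste0("GGGTGACCC", paste(rep("A", 21), collapse = "")),
                     exon2 = "CCCAAATTTGGGAAACCCTTT")
  tr <- translate_extension(d$introns[1, ], d$genome)
  expect_equal(tr$exon_flank_aa, "MAK")
  expect_equal(tr$intron_aa, "G")
  expect_true(tr$terminated_by_stop)
  # same construct on the minus strand must translate identically
  dm <- designed_gene(exon1 = "ATGGCTAAG",
                      intron = paste0("GGGTGACCC", paste(rep("A", 21), collapse = "")),
                      exon2 = "CCCAAATTTGGGAAACCCTTT", strand = "-")
  trm <- translate_extension(dm$introns[1, ], dm$genome)
  expect_equal(trm[, c("exon_flank_aa", "intron_aa", "terminated_by_stop")],
               tr[, c("exon_flank_aa", "intron_aa", "terminated_by_stop")])
})

test_that("immediate stops, frame offsets, and incomplete codons behave", {
  # frame 0, intron begins TAA: empty intronic translation
  d <- designed_gene("ATGAAA", paste0("TAA", paste(rep("C", 27), collapse = "")),
                     "GGGAAATTTCCC")
  tr <- translate_extension(d$introns[1, ], d$genome)
  expect_equal(tr$intron_aa, "")
  expect_true(tr$terminated_by_stop)
  # 10 nt stop-free intron in frame 0: floor(10/3) = 3 residues, no stop
  d2 <- designed_gene("ATGAAA", "GGGGGGGGGG", "CCCAAATTTCCC")
  tr2 <- translate_extension(d2$introns[1, ], d2$genome)
  expect_equal(nchar(tr2$intron_aa), 3L)
  expect_false(tr2$terminated_by_stop)
  # frame 1: junction codon takes 1 exonic + 2 intronic nt => A|AG -> K
  d3 <- designed_gene("ATGGCTA", paste0("AGGGGTGA", paste(rep("C", 22), collapse = "")),
                      "GGGAAATTTCCCAA")
  expect_equal(d3$introns$frame, 1L)
  tr3 <- translate_extension(d3$introns[1, ], d3$genome)
  expect_equal(tr3$exon_flank_aa, "MA")
  expect_equal(tr3$intron_aa, "KG")        # AAG GGG TGA -> K G stop
  expect_true(tr3$terminated_by_stop)
  # non-coding junction is an error; translate_all skips it with a message
  bad <- d3$introns; bad$frame <- NA_integer_
  expect_error(translate_extension(bad[1, ], d3$genome), "non-coding")
  expect_message(out <- translate_all(bad, d3$genome), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("exonic flank is capped at 10 residues", {
  exon <- paste0("ATG", paste(rep("GCT", 30), collapse = ""))  # 31 codons
  d <- designed_gene(exon, paste(rep("G", 40), collapse = ""),
                     "CCCAAATTTCCC")
  tr <- translate_extension(d$introns[1, ], d$genome)
  expect_equal(nchar(tr$exon_flank_aa), 10L)
  expect_equal(tr$exon_flank_aa, paste(rep("A", 10), collapse = ""))
})

test_that("peptide enumeration matches the brute-force oracle", {
  set.seed(17)
  for (i in 1:50) {
    f <- sample(0:10, 1); m <- sample(0:30, 1)
    tr <- data.frame(event_id = "e", exon_flank_aa = rand_aa(f),
                     intron_aa = rand_aa(m), terminated_by_stop = TRUE)
    got <- enumerate_peptides(tr)
    expect_setequal(got$peptide, oracle_peptides(tr$exon_flank_aa, tr$intron_aa))
    expect_true(all(got$n_intronic >= 1L))
    expect_true(all(nchar(got$peptide) == got$length))
  }
})

test_that("the worked enumeration cases hold", {
  tr <- data.frame(event_id = "e",
                   exon_flank_aa = "ACDEFGHIKL", intron_aa = "MNPQR",
                   terminated_by_stop = TRUE)
  expect_equal(nrow(enumerate_peptides(tr)), 20L)          # f=10, m=5
  expect_equal(closed_form_windows(10, 5), 20)
  tr$intron_aa <- ""
  expect_equal(nrow(enumerate_peptides(tr)), 0L)           # nothing intronic
  tr2 <- data.frame(event_id = "e", exon_flank_aa = "",
                    intron_aa = "ACDEFGHI", terminated_by_stop = FALSE)
  expect_equal(nrow(enumerate_peptides(tr2)), 1L)          # single 8-mer
  expect_equal(enumerate_peptides(tr2)$n_intronic, 8L)
})

test_that("self-filtering is exact-match, idempotent, order-independent", {
  set.seed(31)
  prot <- rand_aa(80)
  idx <- build_proteome_index(write_fasta(c(p = prot)))
  planted <- substr(prot, 11, 19)                  # verbatim 9-mer
  near <- planted
  substr(near, 5, 5) <- setdiff(AA20, substr(planted, 5, 5))[1]
  peps <- data.frame(peptide = c(planted, near, rand_aa(10)),
                     event_id = "e", n_intronic = 1L,
                     length = c(9L, 9L, 10L), stringsAsFactors = FALSE)
  out <- filter_self(peps, idx)
  expect_false(planted %in% out$peptide)
  expect_true(near %in% out$peptide)
  again <- filter_self(out, idx)
  expect_equal(again$peptide, out$peptide)         # idempotent
  shuffled <- filter_self(peps[c(3, 1, 2), ], idx)
  expect_setequal(shuffled$peptide, out$peptide)   # order-independent
  empty <- filter_self(peps[0, ], idx)
  expect_equal(nrow(empty), 0L)
})

test_that("HLA allele names normalize to two-field resolution", {
  expect_equal(normalize_hla(c("HLA-A*02:01", "A*02:01", "a02:01",
                               "HLA-B*07:02:01")),
               c("A02:01", "A02:01", "A02:01", "B07:02"))
  expect_error(normalize_hla("notanallele"), "unparseable")
})

test_that("surrogate ranks are deterministic and the cutoff is strict", {
  pr <- surrogate_predictor(seed = 42)
  a <- predict_binding("ACDEFGHI", "HLA-A*02:01", pr)
  b <- predict_binding("ACDEFGHI", "A02:01", pr)
  expect_equal(a$rank_score, b$rank_score)
  expect_true(a$rank_score >= 0 && a$rank_score < 100)
  pr2 <- surrogate_predictor(seed = 43)
  c2 <- predict_binding("ACDEFGHI", "A02:01", pr2)
  expect_false(isTRUE(all.equal(a$rank_score, c2$rank_score)))
})

test_that("NetMHCpan-style prediction files drive binder calls", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("Peptide\tMHC\tEL_Rank",
               "ACDEFGHI\tA02:01\t1.5",
               "ACDEFGHK\tA02:01\t2.0"), f)
  pr <- netmhcpan_file_predictor(f)
  calls <- predict_binding(c("ACDEFGHI", "ACDEFGHK"), "HLA-A*02:01", pr)
  expect_equal(calls$is_binder[calls$peptide == "ACDEFGHI"], TRUE)
  expect_equal(calls$is_binder[calls$peptide == "ACDEFGHK"], FALSE)  # strict <
  expect_error(predict_binding(c("ACDEFGHI", "MISSINGPEP"), "A02:01", pr),
               "never requested|missing prediction")
  expect_error(predict_binding("ACDEFGHI", "A02:01", pr), "never requested")
})

test_that("sample load deduplicates peptides and weights by source RPKM", {
  quant <- data.frame(event_id = c("c:1-2:+:t1", "c:3-4:+:t2"),
                      intron_rpkm = c(4.0, 2.0), passes_filters = TRUE)
  peps <- data.frame(peptide = c("P1P1P1P1", "P2P2P2P2", "P3P3P3P3"),
                     event_id = c("c:1-2:+:t1", "c:1-2:+:t1", "c:3-4:+:t2"),
                     n_intronic = 1L, length = 8L, stringsAsFactors = FALSE)
  calls <- data.frame(
    peptide = c("P1P1P1P1", "P1P1P1P1", "P2P2P2P2", "P3P3P3P3"),
    allele = c("A02:01", "B07:02", "A02:01", "A02:01"),
    rank_score = 0.5, is_binder = TRUE, stringsAsFactors = FALSE)
  load <- compute_sample_load(calls, quant, peps, "s1")
  expect_equal(load$neoag_load, 3L)                 # dedupe across alleles
  expect_equal(load$weighted_load, 4.0 * 2 + 2.0 * 1)
  # duplicated call records change nothing
  load2 <- compute_sample_load(rbind(calls, calls), quant, peps, "s1")
  expect_equal(load2$neoag_load, load$neoag_load)
  expect_equal(load2$weighted_load, load$weighted_load)
  # no binders
  none <- calls; none$is_binder <- FALSE
  load0 <- compute_sample_load(none, quant, peps, "s1")
  expect_equal(load0$neoag_load, 0L)
  expect_equal(load0$weighted_load, 0)
  # a binder with no source event is a pipeline-order violation
  orphan <- calls; orphan$peptide[1] <- "ZZZZZZZZ"
  expect_error(compute_sample_load(orphan, quant, peps, "s1"), "no source")
  # alternative accounting: peptide-allele pairs / RPKM once per event
  expect_equal(compute_sample_load(calls, quant, peps, "s1",
                                   load_unit = "peptide-allele")$neoag_load, 4L)
  expect_equal(compute_sample_load(calls, quant, peps, "s1",
                                   weighted_mode = "rpkm_once")$weighted_load, 6)
})

test_that("adding an allele never decreases the load", {
  set.seed(55)
  quant <- data.frame(event_id = "c:1-2:+:t1", intron_rpkm = 1,
                      passes_filters = TRUE)
  peps <- data.frame(peptide = replicate(30, rand_aa(9)),
                     event_id = "c:1-2:+:t1", n_intronic = 1L, length = 9L,
                     stringsAsFactors = FALSE)
  pr <- surrogate_predictor(1, allele_shift = c("A02:01" = -90))
  alleles <- c("A01:01", "A02:01", "B07:02")
  loads <- vapply(1:3, function(k) {
    calls <- predict_binding(peps$peptide, alleles[1:k], pr)
    compute_sample_load(calls, quant, peps, "s")$neoag_load
  }, 0L)
  expect_true(all(diff(loads) >= 0))
})

test_that("allele summary reports carrier frequency and presented peptides", {
  genotypes <- data.frame(
    sample_id = rep(c("s1", "s2", "s3", "s4", "s5"), each = 2),
    allele = c("A02:01", "B07:02", "A02:01", "C04:01", "A01:01", "C04:01",
               "A01:01", "B07:02", "A01:01", "C04:01"))
  set.seed(7)
  peps <- replicate(40, rand_aa(9))
  # B07:02 gets systematically stronger ranks
  pr <- surrogate_predictor(3, allele_shift = c("B07:02" = -95))
  calls_by_sample <- lapply(split(genotypes, genotypes$sample_id),
                            function(g) predict_binding(peps, g$allele, pr))
  summ <- cohort_allele_summary(calls_by_sample, genotypes)
  expect_equal(summ$carrier_frequency[summ$allele == "A02:01"], 0.4)
  expect_equal(summ$carrier_frequency[summ$allele == "B07:02"], 0.4)
  top <- summ$allele[which.max(summ$n_presented_peptides)]
  expect_equal(top, "B07:02")
  # carried allele with no binders counts zero
  no_bind <- lapply(calls_by_sample, function(x) { x$is_binder <- FALSE; x })
  summ0 <- cohort_allele_summary(no_bind, genotypes)
  expect_true(all(summ0$n_presented_peptides == 0L))
})

test_that("shared-peptide fractions use a strict threshold", {
  sets <- c(replicate(6, "PEPTIDEA", simplify = FALSE),
            replicate(5, "PEPTIDEB", simplify = FALSE),
            replicate(89, character(0), simplify = FALSE))
  tab <- shared_peptide_frequency(sets, threshold = 0.05)
  expect_equal(tab$sample_fraction[tab$peptide == "PEPTIDEA"], 0.06)
  expect_true(tab$shared_flag[tab$peptide == "PEPTIDEA"])
  expect_equal(tab$sample_fraction[tab$peptide == "PEPTIDEB"], 0.05)
  expect_false(tab$shared_flag[tab$peptide == "PEPTIDEB"])
  all_shared <- shared_peptide_frequency(replicate(4, "PEPTIDEC",
                                                   simplify = FALSE))
  expect_equal(all_shared$sample_fraction, 1)
  expect_true(all_shared$shared_flag)
})
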