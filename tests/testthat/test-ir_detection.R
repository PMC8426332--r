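test_that("region TPM sums to 1e6 and follows the rate definition", {
  introns <- quant_introns(n = 3L)
  counts <- quant_counts(introns, intron_count = c(10L, 50L, 0L),
                         up_count = 200L, down_count = 180L)
  q <- compute_region_tpm(counts, introns)
  uni <- unique(c(q$intron_tpm,
                  rep(NA, 0)))  # intron TPMs are per unique region here
  # reconstruct the universe sum: 3 introns + 6 distinct exons
  rates <- c(counts$intron_count / 100, counts$up_count / 200,
             counts$down_count / 200)
  expect_equal(q$intron_tpm, (counts$intron_count / 100) / sum(rates) * 1e6)
  # flank mean aggregation
  expect_equal(q$flank_tpm,
               ((counts$up_count / 200) + (counts$down_count / 200)) / 2 /
                 sum(rates) * 1e6)
  expect_equal(q$tpm_ratio, q$intron_tpm / q$flank_tpm)
})

test_that("TPM over the universe totals 1e6 whenever any count is nonzero", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    introns <- quant_introns(n)
    counts <- quant_counts(introns,
                           intron_count = sample(0:100, n, replace = TRUE),
                           up_count = sample(0:400, n, replace = TRUE),
                           down_count = sample(0:400, n, replace = TRUE))
    q <- compute_region_tpm(counts, introns)
    rates <- c(counts$intron_count / 100, counts$up_count / 200,
               counts$down_count / 200)
    total <- sum((c(counts$intron_count / 100) / sum(rates) * 1e6)) +
      sum((counts$up_count / 200) / sum(rates) * 1e6) +
      sum((counts$down_count / 200) / sum(rates) * 1e6)
    expect_equal(total, 1e6, tolerance = 1e-6)
    expect_equal(q$intron_tpm, counts$intron_count / 100 / sum(rates) * 1e6)
  }
})

test_that("shared flanking exons enter the TPM denominator once", {
  # two introns of one transcript share the middle exon
  introns <- data.frame(
    event_id = c("c:200-300:+:t", "c:500-600:+:t"),
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    intron_start = c(200L, 500L), intron_end = c(300L, 600L),
    up_start = c(100L, 300L), up_end = c(200L, 500L),
    down_start = c(300L, 600L), down_end = c(500L, 700L),
    frame = 0L, stringsAsFactors = FALSE)
  counts <- data.frame(event_id = introns$event_id,
                       intron_count = c(20L, 30L),
                       up_count = c(100L, 400L), down_count = c(400L, 90L),
                       library_size = 1000L)
  q <- compute_region_tpm(counts, introns)
  # universe: 2 introns (len 100) + exons [100,200),[300,500),[600,700)
  rates <- c(20 / 100, 30 / 100, 100 / 100, 400 / 200, 90 / 100)
  expect_equal(q$intron_tpm, c(0.2, 0.3) / sum(rates) * 1e6)
})

test_that("RPKM follows its definition", {
  introns <- quant_introns(1L, intron_len = 1000L)
  counts <- quant_counts(introns, 100L, 200L, 200L, library_size = 1e6L)
  q <- compute_region_tpm(counts, introns)
  expect_equal(q$intron_rpkm, 100)
})

test_that("retention filters are strict at both boundaries", {
  introns <- quant_introns(1L)
  cfg <- filter_config()
  mk <- function(ic, uc, dc, ratio) {
    data.frame(event_id = "e", intron_count = ic, up_count = uc,
               down_count = dc, library_size = 1000L,
               intron_tpm = 1, flank_tpm = 1, tpm_ratio = ratio,
               intron_rpkm = 1, passes_filters = NA)
  }
  expect_true(apply_ir_filters(mk(15, 20, 25, 0.2), cfg)$passes_filters)
  expect_false(apply_ir_filters(mk(10, 20, 25, 0.2), cfg)$passes_filters)
  expect_false(apply_ir_filters(mk(50, 60, 70, 0.5), cfg)$passes_filters)
  expect_false(apply_ir_filters(mk(50, 60, 70, 0.05), cfg)$passes_filters)
  expect_false(apply_ir_filters(mk(50, 10, 70, 0.2), cfg)$passes_filters)
  expect_false(apply_ir_filters(mk(50, 60, 10, 0.2), cfg)$passes_filters)
  # undefined ratio fails
  expect_false(apply_ir_filters(mk(50, 60, 70, NA), cfg)$passes_filters)
})

test_that("raising min_region_count never enlarges the passing set", {
  set.seed(9)
  introns <- quant_introns(20L)
  counts <- quant_counts(introns,
                         intron_count = sample(5:40, 20, replace = TRUE),
                         up_count = sample(5:400, 20, replace = TRUE),
                         down_count = sample(5:400, 20, replace = TRUE))
  passing <- lapply(c(5, 10, 20), function(mc) {
    cfg <- filter_config(min_region_count = mc)
    call_sample_events(apply_ir_filters(
      compute_region_tpm(counts, introns, cfg), cfg))
  })
  expect_true(all(passing[[2]] %in% passing[[1]]))
  expect_true(all(passing[[3]] %in% passing[[2]]))
})

test_that("events are deduplicated by genomic interval", {
  q <- data.frame(event_id = c("c:1-10:+:t1", "c:1-10:+:t2", "c:20-30:+:t1"),
                  passes_filters = TRUE)
  expect_length(call_sample_events(q), 2L)
  expect_length(call_sample_events(q, dedupe = FALSE), 3L)
})

test_that("normal panel is the union and subtraction is a set difference", {
  expect_setequal(build_normal_panel(list(c("c:1-2:+:a", "c:3-4:+:b"),
                                          c("c:3-4:+:b", "c:5-6:+:c"))),
                  c("c:1-2:+:a", "c:3-4:+:b", "c:5-6:+:c"))
  expect_warning(p <- build_normal_panel(list()), "empty")
  expect_length(p, 0L)
  x <- c("c:1-2:+:a", "c:3-4:+:b", "c:5-6:+:c")
  expect_equal(subtract_normal(x, "c:3-4:+:b"), x[-2])
  expect_equal(subtract_normal(x, character(0)), x)
  expect_length(subtract_normal(x, x), 0L)
  # comparison is by genomic interval, not transcript
  expect_length(subtract_normal("c:1-2:+:t1", "c:1-2:+:t9"), 0L)
})

test_that("BAM counting matches a brute-force overlap oracle", {
  introns <- data.frame(
    event_id = "chrT:200-300:+:t1", gene_id = "g", transcript_id = "t1",
    chrom = "chrT", strand = "+", intron_start = 200L, intron_end = 300L,
    up_start = 100L, up_end = 200L, down_start = 300L, down_end = 400L,
    frame = 0L, stringsAsFactors = FALSE)
  set.seed(21)
  reads <- data.frame(
    qname = sprintf("r%02d", 1:30),
    pos = sample(80:380, 30, replace = TRUE),
    mapq = sample(c(255L, 255L, 255L, 3L), 30, replace = TRUE),
    cigar = "40M", nh = NA_integer_, stringsAsFactors = FALSE)
  # hand-placed special cases
  reads <- rbind(reads,
    data.frame(qname = "contained", pos = 231L, mapq = 255L, cigar = "40M",
               nh = NA_integer_),
    data.frame(qname = "spliced_skip", pos = 51L, mapq = 255L,
               cigar = "150M100N50M", nh = NA_integer_),
    data.frame(qname = "multimapper", pos = 240L, mapq = 255L, cigar = "40M",
               nh = 3L),
    data.frame(qname = "nh_unique_lowmapq", pos = 250L, mapq = 1L,
               cigar = "40M", nh = 1L))
  bam <- sam_to_bam(reads)
  got <- count_regions(bam, introns)
  expect_equal(got$intron_count, oracle_count(reads, 200L, 300L))
  expect_equal(got$up_count, oracle_count(reads, 100L, 200L))
  expect_equal(got$down_count, oracle_count(reads, 300L, 400L))
  # the spliced read skips the intron but supports both flanks
  solo <- reads[reads$qname == "spliced_skip", , drop = FALSE]
  bam2 <- sam_to_bam(solo)
  got2 <- count_regions(bam2, introns)
  expect_equal(got2$intron_count, 0L)
  expect_equal(got2$up_count, 1L)
  expect_equal(got2$down_count, 1L)
  expect_equal(got2$library_size, 1L)
  # empty BAM: all zero
  empty <- sam_to_bam(reads[0, , drop = FALSE])
  got3 <- count_regions(empty, introns)
  expect_equal(got3$intron_count + got3$up_count + got3$down_count, 0L)
  # contig mismatch is an error naming the contig
  introns_bad <- introns; introns_bad$chrom <- "chrZ"
  introns_bad$event_id <- "chrZ:200-300:+:t1"
  expect_error(count_regions(bam, introns_bad), "chrZ")
})
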