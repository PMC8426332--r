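---
title: "Calling intron-retention neoantigens and modeling their prognostic effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling intron-retention neoantigens and modeling their prognostic effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoIR)
```

## Background and model

Intron retention (IR) is a splicing outcome in which an intron survives into
the mature, polyadenylated transcript. When a retained intron sits inside a
coding region, ribosomes read from the upstream exon into intronic sequence
during the pioneer round of translation, before nonsense-mediated decay
removes the transcript. The resulting intron-encoded peptides are absent
from the normal proteome, so those that bind a patient's MHC class I
molecules are candidate tumor neoantigens. In hematological cancers such as
multiple myeloma, where somatic mutation burden is comparatively low, this
splicing-derived antigen source can dominate the presented repertoire, and
a patient's IR-neoantigen load carries prognostic information.

`neoIR` implements this calling chain end to end:

1. **IR event detection.** For every transcript intron, count uniquely
   mapped reads over the intron and its two flanking exons. An event is
   retained in a sample when all three region counts strictly exceed 10 and
   the intron/flank TPM ratio lies strictly inside (0.05, 0.5). The lower
   ratio bound removes baseline noise; the upper bound removes regions that
   look like unannotated exons rather than partially retained introns.
2. **Normal-panel subtraction.** Events passing the same filters in at
   least one normal sample form a panel that is removed from every tumor's
   event set; peptides from those events are expected to be tolerated.
3. **Translation by ORF extension.** The upstream exon's reading frame is
   extended through the junction into the intron with the standard codon
   table, stopping at the first in-frame stop codon.
4. **Neoepitope enumeration.** All 8--11-mers containing at least one
   intron-encoded residue are enumerated; peptides that occur verbatim in
   the reference proteome are removed (exact match, no I/L equivalence).
5. **Binding prediction.** Each candidate is scored against the patient's
   HLA class I alleles; a percentile rank strictly below 2 calls a binder.
   Predictions come from a pluggable backend: an adapter over
   NetMHCpan-4.1-style tabular output, or a deterministic uniform surrogate
   for testing and calibration.
6. **Load and outcome.** The count load is the number of unique binder
   peptides per sample; the expression-weighted load multiplies each
   producing event's intron RPKM by its number of unique binder peptides.
   Loads are median-dichotomized and compared by Kaplan--Meier curves, the
   log-rank test, and Cox proportional-hazards regression.

## Region-level quantification

TPM and RPKM are computed per genomic region, not per transcript. The TPM
universe is the set of all intron and flanking-exon regions of the
annotation: with $r_i = c_i / \ell_i$ the read rate of region $i$,
$\mathrm{TPM}_i = 10^6 r_i / \sum_j r_j$. A region shared between two
events (an exon flanking two introns) enters the denominator once. The
flank TPM is the arithmetic mean of the two flanking-exon TPMs by default
(`filter_config(flank_agg = "min")` gives the conservative alternative).
RPKM uses the number of unique reads counted over the region universe as
the library size; a configuration option to substitute total aligned reads
is deliberately out of scope for the count-table input path, where only
universe counts exist.

Read counting accepts either a coordinate-sorted BAM (a read supports a
region when any aligned CIGAR block overlaps it by at least 1 bp, so a
spliced read whose N gap spans the intron supports excision, not
retention; uniqueness is NH == 1 when the tag exists, else MAPQ >= 255,
STAR's unique-mapper convention) or a plain count table
(`sample_id, event_id, intron_count, up_count, down_count, library_size`),
which keeps the pipeline testable without alignments.

## Translation details and tunable parameters

Introns are modeled per transcript: flanking exons and reading frame are
transcript properties, and the event identifier embeds the transcript.
Deduplication to unique genomic intervals happens at reporting time
(`call_sample_events`), so an intron shared by two isoforms is counted
once per sample.

The junction frame is the cumulative coding length upstream of the
junction mod 3 and is defined only when the upstream exon's CDS reaches
the junction; events with non-coding upstream flanks are skipped rather
than rescued with a longest-ORF heuristic. The exonic flank kept for
enumeration is capped at 10 residues (maximum peptide length minus one):
every junction-spanning 8--11-mer with at least one intronic residue is
reachable and nothing fully exonic beyond that need is enumerated. A codon
spanning the junction counts as intron-encoded because it uses at least
one intronic nucleotide. Translation never reads through into the
downstream exon: when the intron ends before an in-frame stop, the last
complete intron codon terminates the extension. An ambiguous base (N)
truncates translation at that codon.

Key parameters, defaults, and meaning:

| parameter | default | meaning |
|---|---|---|
| `min_region_count` | 10 (exclusive) | read support floor for intron and both flanks |
| `ratio_low`, `ratio_high` | 0.05, 0.5 (both exclusive) | retention window on the intron/flank TPM ratio |
| `flank_agg` | mean | aggregation of the two flanking-exon TPMs |
| `mapq_unique` | 255 | MAPQ accepted as unique without an NH tag |
| `rank_cutoff` | 2.0 (strict <) | percentile-rank binder threshold |
| `load_unit` | peptide | unique peptides vs peptide-allele pairs |
| `weighted_mode` | per_peptide | RPKM x binder count vs RPKM once per event |

## Survival statistics

The outcome layer is implemented from formulas: the product-limit
estimator (deaths before censorings at ties), the two-group log-rank test
with hypergeometric variance, Newton--Raphson maximization of the Cox
partial likelihood with Breslow ties by default (Efron by flag), Wald
standard errors from the observed information, and confidence intervals
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$. Convergence requires a maximum
absolute score below 1e-8 within 50 iterations with step halving;
coefficients above 20 in absolute value are flagged as likely complete
separation. Samples exactly at the median load go to the "low" group: high
load means strictly above the median. Categorical covariates are one-hot
encoded against their first level, with "low" forced as the reference for
load groups. P-values are two-sided and uncorrected, matching how a single
prespecified load comparison is reported. The test suite cross-checks
every estimator against the survival package and `cor.test`, which are
never used in the implementation itself.

## The surrogate predictor

The built-in surrogate maps each (peptide, allele, seed) triple through a
32-bit FNV-1a hash to a private RNG seed and draws one uniform rank on
[0, 100). It is deterministic, order-independent, and calibrated: at the
default cutoff the expected binder fraction is 2%, which the test suite
verifies within three binomial standard deviations over 10,000 pairs. An
optional per-allele rank offset lets tests construct alleles with
systematically stronger presentation. The surrogate models no peptide
chemistry whatsoever; real analyses should use the NetMHCpan file adapter.

## What the synthetic study emulates

`sim_config()` defines the package's reference study: 20 genes of 4 exons
on their own contigs (alternating strands), CDS spanning every exon with
no internal stop so every junction frame is known; 50 tumor and 5 normal
samples; negative-binomial exon coverage (mean 300 reads per exon region,
dispersion 0.02) — overdispersion is included specifically to stress the
threshold logic; a quarter of introns planted as tumor-specific retained
events with target TPM ratios drawn from (0.1, 0.4), realized against each
sample's actual flank coverage; six events planted in normals (and
tumors) that the panel must remove; decoy events violating exactly one
filter clause each (intron count pinned at 10 with an in-window ratio, or
ratios of 0.7 / 0.02 with counts above threshold — intron lengths per
class are chosen to make this geometrically consistent); per-sample
retention probabilities uniform on (0.3, 0.9) to spread event counts;
6-allele genotypes from a 12-allele pool; and exponential survival with a
2-fold hazard for above-median load and roughly 30% censoring. Planted
introns carry a 5--12-codon open reading frame before a stop, and a few
junction 9-mers of planted events are appended to the proteome as labeled
self-decoys that the self-filter must remove.

These sizes keep a full simulate-plus-pipeline run around ten seconds and
the whole validation suite within a desktop coffee break, while leaving
every stage's decision boundary exercised from both sides.

What it does **not** emulate: read-level artifacts (the counts are drawn,
not aligned), positional coverage bias within regions, overlapping genes
and shared exons across genes, isoform mixtures, sequencing errors, HLA
linkage structure, and any real peptide-MHC chemistry. Passing tests
demonstrate that the implementation computes the defined quantities
correctly under controlled conditions, not that the biological discovery
replicates; cohort-scale numbers from patient data are outside what a
synthetic study of this size can reproduce.

## Numerical and design choices

- Internal coordinates are 0-based half-open everywhere; GTF (1-based
  inclusive) converts at the file boundary only.
- "Upstream" always means 5' in transcription order; minus-strand
  sequence extraction reverse-complements before translation.
- An undefined TPM ratio (zero flank TPM, or an all-zero sample) fails
  the filters rather than erroring.
- The self-peptide index is exact-match on the 20 standard residues;
  k-mer windows containing B/J/O/U/X/Z or `*` are never indexed.
- A load-event correlation check conditions on a uniform binder
  probability per event (one shared allele set): patient-specific
  genotypes modulate per-sample binder rates about 2-fold, which is
  realistic but deliberately excluded from that particular invariant.
- Cox score statistics at zero equal the log-rank statistic on tie-free
  data; with ties the hypergeometric correction makes them differ, which
  is why the equivalence checks simulate continuous times.

## Known limitations

- No junction-read splice index (IRFinder-style IR ratio): only the two
  count/ratio filters are implemented, by design.
- No multi-mapper rescue, GFF3 input, alternative codon tables, or
  selenocysteine handling.
- The normal panel is presence-based (>= 1 normal); no frequency
  threshold is exposed.
- The clinical layer has no stratified Cox, time-varying covariates, or
  competing risks.
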