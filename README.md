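# neoIR

Intron-retention-derived neoantigen calling and prognostic modeling for
bulk RNA-seq cohorts.

Tumors with few somatic mutations can still present abundant
tumor-specific antigens when mis-splicing leaves introns in mature mRNA:
ribosomes extend the upstream exon's open reading frame into intronic
sequence during the pioneer round of translation, producing peptides the
thymus has never seen. `neoIR` turns region-level read counts into
per-patient intron-retention (IR) neoantigen loads and tests whether load
predicts overall survival. It is aimed at computational immunologists and
cancer genomicists who have aligned RNA-seq (or region count tables), HLA
class I genotypes, and clinical follow-up.

## The method

For each transcript intron with flanking exons, an IR event is called in a
sample when

- read counts of the intron and of **both** flanking exons are `> 10`
  (strict), and
- the intron/flank TPM ratio lies strictly inside `(0.05, 0.5)`, where
  region TPM is `10^6 * rate_i / sum(rates)` over the universe of all
  intron and flanking-exon regions, and the flank value is the mean of the
  two exon TPMs.

Events passing the same filters in at least one normal sample form a panel
that is subtracted from every tumor event set. Surviving events are
translated by ORF extension (standard codon table, stop at the first
in-frame stop), segmented into 8–11-mers with at least one intron-encoded
residue, purged of exact proteome matches, and scored against the
patient's HLA class I alleles; percentile rank `< 2` calls a binder.
Per-sample load is the number of unique binder peptides
(`neoag_load`), or the RPKM-weighted variant (`weighted_load =
sum over events of RPKM x unique binder peptides`). Loads are
median-dichotomized (ties low) and associated with overall survival via
Kaplan–Meier curves, the log-rank test, and Cox proportional-hazards
regression (Breslow ties; all estimators implemented from formulas and
cross-checked against the survival package in the test suite).

Binding predictions are pluggable: an adapter for NetMHCpan-4.1-style
tabular files, or a deterministic uniform surrogate
(`surrogate_predictor()`) for testing and calibration.

## Worked example

The package ships a synthetic-study generator whose defaults plant 15
tumor-specific IR events, a 6-event normal panel, and boundary decoys into
a 20-gene annotation with 50 tumor and 5 normal samples:

```r
library(neoIR)
sim <- simulate_study(sim_config(seed = 1), "demo")
run <- sim$pipeline
head(run$loads, 5)
#>   sample_id n_events neoag_load weighted_load
#> 1   tumor01        4         11      132783.3
#> 2   tumor02       10         33      451098.2
#> 3   tumor03       11         30      406038.4
#> 4   tumor04        7         26      370429.6
#> 5   tumor05       14         33      329587.3

st <- outcome_stats(run$loads, sim$clinical$clinical)
st$summary$logrank_p
#> [1] 0.002636439
st$cox_table[1, c("term", "hazard_ratio", "ci95_low", "ci95_high", "wald_p")]
#>             term hazard_ratio ci95_low ci95_high  wald_p
#> 1 load_grouphigh        2.994    1.424      6.30 0.00382
```

`n_events` is the number of tumor-specific IR events per sample after
panel subtraction; `neoag_load` counts unique MHC-binding non-self
peptides. The simulated cohort plants a 2-fold hazard for above-median
load, and the log-rank test and univariate Cox fit recover a significant
high-load risk (the hazard-ratio estimate is noisy at n = 50, as the wide
confidence interval shows). On this fixture the pipeline recovers exactly
the 15 planted events (the 6 panel events are subtracted) and removes
every planted self-decoy peptide.

To run on your own data, write a `pipeline.yaml` (see the one
`simulate_study()` drops beside its fixtures) pointing at your GTF, genome
and proteome FASTA, count table or BAMs, genotypes, and clinical table,
then `run_pipeline(read_pipeline_config("pipeline.yaml"))` or use the CLI
at `inst/cli/neoir.R` (`simulate`, `run`, `stats` subcommands).

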