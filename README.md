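# mitocirc

Quantification and biomarker analysis of transcripts that span the
linearization junction of a circular genome — built around the mitochondrial
D-loop long non-coding RNAs **MDL1** (heavy strand, 15,954..576 of the
16,569 bp human mitogenome) and **MDL1AS** (light strand, 16,024..407).

Reference assemblies cut the circular mitochondrial genome exactly at the
heavy-strand replication origin, so reads from transcripts bridging that cut
have no contiguous placement and standard RNA-seq pipelines silently lose
them. `mitocirc` provides, for bioinformaticians and biostatisticians
working on such genes:

* **Circular coordinate algebra** — rotation of the reference to a new
  origin (`pos' = ((pos - p) mod L) + 1`), endpoint-wise annotation liftover
  that preserves span and strand, junction-padded linear references
  (`pad_k = read_length - 1` makes every junction read mappable exactly
  once), and FASTA/GTF I/O with a two-exon encoding for wrap-around models.
* **A strand-aware read simulator** for circular transcript models with a
  sidecar truth table.
* **A desk-scale seed-and-extend mapper** (exact 20-mer seeds, Hamming
  extension, both strands) with featureCounts-style overlap counting and
  RPKM: `count * 1e9 / (length_bp * mapped_total)`.
* **Synthetic patient cohorts** — moment-matched lognormal RPKM per group,
  exponential survival with rate
  `h0 * HR^[expression < cutoff]`, administrative censoring plus dropout.
* **Survival-biomarker statistics from first principles** — empirical ROC
  with DeLong 95% CI (trapezoid AUC provably equal to the Mann–Whitney
  form), Youden-index cutoff `J = sens + spec - 1` with Wilson CIs,
  Kaplan–Meier, log-rank (Mantel–Cox), univariate Cox with Efron ties, and
  the ANOVA/Sidak/Welch/chi-square/Benjamini–Hochberg battery for group
  comparisons.

## Worked example

Simulate a stranded library from the two D-loop genes on a synthetic
16,569 bp circle, then quantify it on the naive linearization and on a
reference rotated to origin 8,000 with a 99 bp junction pad:

```r
library(mitocirc)
set.seed(11)
genome <- circ_seq("chrM", paste(sample(c("A","C","G","T"), 16569,
                                        replace = TRUE), collapse = ""))
genes <- list(gene_model("MDL1",   start = 15954, end = 576, strand = "heavy"),
              gene_model("MDL1AS", start = 16024, end = 407, strand = "light"))
sim <- simulate_reads(genome, genes,
                      sim_config(read_length = 100,
                                 n_reads = c(MDL1 = 2000, MDL1AS = 2000),
                                 error_rate = 0.001,
                                 strandedness = "reverse", seed = 11))
junction_loss_report(sim, genome, genes, origin = 8000)
#>          gene n_truth n_junction count_naive count_rotated
#> MDL1     MDL1    2000        162        1838          2000
#> MDL1AS MDL1AS    2000        244        1756          2000
```

The naive reference loses *exactly* the junction-spanning reads (162 and
244 here, an 8–12% under-count); the rotated, padded reference recovers all
of them. Now a synthetic 69-patient cohort with the published expression
structure and a true prognostic cutoff at 1980 RPKM:

```r
cohort <- simulate_cohort(default_paper_cohort(), seed = 11)
biomarker_report(cohort, "MDL1AS")
#> == biomarker report: MDL1AS (n = 69, 4 excluded) ==
#> <roc_curve> AUC = 0.6648 (95% CI 0.5265-0.8030), 36 pos / 29 neg
#> <cutoff_result> cutoff = 1441.11 (J = 0.3496), sens = 0.694 (0.531-0.820),
#>                 spec = 0.655 (0.473-0.801)
#> <logrank_result> chi-square = 4.3270 (df = 1), p = 0.03751
#> <cox_result> HR = 1.8469 (95% CI 1.0273-3.3205), p = 0.04037
```

Reading: patients are labeled 5-year survivors/nonsurvivors (4 censored
before 60 months are excluded from classification), higher MDL1AS predicts
survival (AUC 0.66 at this n and seed), the Youden-optimal observed cutoff
is 1441 RPKM, and dichotomizing there gives low expressors a hazard ratio of
1.85 (log-rank p = 0.038). At n = 69 these quantities are intentionally
noisy; the test suite checks their convergence at larger n.

A command-line front end covering the same pipeline is installed at
`system.file("cli", "mitocirc", package = "mitocirc")` (subcommands
`rotate`, `simulate-reads`, `quantify`, `simulate-cohort`, `biomarker`).

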