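# apobecscan

Quantifies APOBEC-driven mutagenesis in tumor cohorts and its downstream
clinical and immunological correlates, from somatic variant calls and a
reference genome. Written for cancer-genomics analysts working with
WES/WGS cohorts (with optional bulk and single-cell expression data)
who need the APOBEC enrichment score and the statistics that usually
travel with it in one tested toolbox.

## What it computes

**APOBEC mutagenesis enrichment score (AMS).** For each sample, over
eligible mutated cytosines (and guanines, read on the reverse
complement):

```
AMS = (mut_TCW / mut_C) / (ctx_TCW / ctx_C)
```

where `mut_TCW / mut_C` is the fraction of mutated C/G falling in TCW
motifs (T-C-W with W = A or T; WGA on the opposite strand), and the
context fractions count TCW+WGA motifs and C+G bases inside the
41-nucleotide window centered on each mutation. AMS ≈ 1 means no motif
preference; APOBEC-driven samples score well above 1.

Around that core:

- pyrimidine-normalized 96-channel mutation catalogs from VCF/MAF +
  FASTA, with exclusion accounting and TMB (nonsynonymous SNVs + indels
  per Mb);
- YTCA/RTCA tetranucleotide attribution separating APOBEC3A-like
  (pyrimidine at −2) from APOBEC3B-like (purine at −2) activity;
- signature-activity refitting by nonnegative least squares against a
  COSMIC-style reference catalog, with cohort-level pruning and
  etiology-group fractions;
- survival dichotomization at the minimum log-rank cutpoint (with a
  permutation-adjusted p-value), Cox models with Efron ties, quantile
  grouping;
- two-stage Fisher mutation-pathway enrichment between cohort groups
  with Benjamini–Hochberg control;
- bulk expression scores (CYT = geometric mean of PRF1 and GZMA,
  score-correlated gene ranking, gene-set means) and single-cell
  statistics (QC filtering, Ro/e cell-type enrichment, reference-gene
  signatures, seeded downsampling);
- seeded synthetic-cohort generators (genomes, signature-mixture
  mutation cohorts with a controllable YTCA/RTCA balance, survival,
  copula expression, single-cell cohorts) that emit truth bundles for
  recovery testing.

See `vignettes/apobec-mutagenesis.Rmd` for the methods account.

## Worked example

Simulate a 24-sample cohort with a quarter of the mutation burden
planted on two APOBEC-analog signatures and an A3A-dominant (70%
preceding-pyrimidine) motif balance, then recover everything:

```r
library(apobecscan)

sigs <- read_signature_catalog(system.file("extdata",
  "signatures_8_synthetic.tsv", package = "apobecscan"))
act <- sample_activity_matrix(sigs, n_samples = 24, total_mutations = 400,
  group_share = 0.25, group_cols = c("APOBEC.CT", "APOBEC.CG"), seed = 7)
ref <- gen_reference(100000, gc_fraction = 0.45, seed = 7)
sim <- gen_cohort_mutations(ref$genome, act, sigs,
  ytca_pyrimidine_prob = 0.7, seed = 7)

catalog <- build_catalog(sim$records, ref$genome)
fit <- refit_activities(catalog, sigs, prune_frac = 0.01)
etiology_fractions(fit, list(APOBEC = c("APOBEC.CT", "APOBEC.CG")))
#>    group  percent
#> 1 APOBEC 26.53268
#> 2 Others 73.46732

head(compute_ams(sim$records, ref$genome), 3)
#>   sample n_mut_tcw n_mut_c n_ctx_tcw n_ctx_c      ams
#> 1   S001        81     179       522    3047 2.641399
#> 2   S002        84     164       508    2790 2.813040
#> 3   S003        78     176       529    2996 2.509967

attr(ytca_rtca_counts(sim$records, ref$genome), "cohort")
#>   ytca rtca ytcw rtcw ratio_ytca_rtca ratio_ytcw_rtcw
#> 1  748  334 1671  719        2.239521        2.324061
```

The refit recovers the planted APOBEC share (26.5% vs the cohort's
realized draw around 25%), every sample's AMS sits far above the null
value of 1, and the cohort YTCA:RTCA ratio lands near the planted
7:3 ≈ 2.33.

Dichotomizing a simulated survival cohort (hazard ratio 0.4 planted
above score 1.0, n = 169) and adjusting for covariates:

```r
surv <- gen_survival(169, cutoff = 1.0, hr = 0.4, seed = 7)
cut <- optimal_cutoff(setNames(surv$survival$score,
                               surv$survival$sample), surv$survival)
cut
#> Optimal cutoff 1.028 (log-rank p = 7.2e-06; 96 high / 73 low)
subset(cox_ph(surv$survival, cut$labels,
              covariates = c("age", "gender", "stage")),
       term == "grouphigh")
#>        term        hr    ci_low   ci_high            p
#> 1 grouphigh 0.3861743 0.2517789 0.5923078 1.301955e-05
```

The recovered cutpoint (1.028) sits next to the planted threshold and
the adjusted hazard ratio (0.39, CI 0.25–0.59) brackets the planted
0.4: high-AMS patients live longer under this generative model.

## Layout

- `R/` — implementation (catalogs, AMS/motifs, refitting, survival,
  enrichment, expression, single-cell, generators)
- `inst/extdata/` — small plain-text fixtures (120-bp AMS genome + VCF,
  toy catalog VCF, synthetic 8-signature reference)
- `tests/testthat/` — unit, property and end-to-end recovery suites with
  independent oracles (brute-force window scans, exhaustive
  hypergeometric enumeration, hand step-up BH, textbook log-rank)
- `vignettes/apobec-mutagenesis.Rmd` — the methods vignette
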