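---
title: "Quantifying APOBEC mutagenesis in tumor cohorts"
author: "apobecscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying APOBEC mutagenesis in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecscan)
```

## The problem

APOBEC3 cytidine deaminases (chiefly A3A and A3B) attack single-stranded
DNA and leave a recognizable scar in tumor genomes: C>T and C>G changes
concentrated at TCW trinucleotides (W = A or T), mirrored as WGA on the
opposite strand. In esophageal squamous cell carcinoma and many other
cancers this process accounts for a large slice of the mutation burden
and correlates with immune infiltration and survival. `apobecscan`
implements the computational core of that style of analysis for somatic
variant cohorts: mutation catalogs, the APOBEC enrichment score, motif
attribution of A3A- vs A3B-like activity, signature-activity refitting,
survival dichotomization, mutation-pathway enrichment, bulk and
single-cell immune scoring, and seeded cohort simulators that close the
loop with known truth.

## Mutation catalogs

Every SNV is assigned one of 96 channels by its pyrimidine-normalized
trinucleotide context: when the mutated base is a purine, the
substitution and both flanks are read through the reverse complement, so
a G>A change in a `TGA` context is the channel `T[C>T]A`. Channels are
ordered substitution-major (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`,
each crossed with the 16 flank pairs); `sbs96_channels()` is the single
source of that order. Variants that cannot be classified — indels,
reference mismatches, contig-edge positions, N in a flank — are excluded
from the matrix but tallied per sample, so the conservation identity
`row sums + exclusions = input SNVs` always holds. Coordinates are
1-based and closed everywhere, the convention of the surrounding R and
Bioconductor ecosystem; VCF and MAF positions are used as-is.

Tumor mutation burden is counted as nonsynonymous SNVs plus indels per
megabase of target territory. The target size is a parameter
(`target_mb`, default 38, a typical whole-exome footprint) because the
appropriate denominator depends on the capture design; variants without
an effect annotation only count when `tmb_include_unknown`-style opt-in
(`include_unknown = TRUE`) is chosen.

## The APOBEC enrichment score

For each sample, over the eligible mutated cytosines (and guanines, read
on the complement):

$$
\mathrm{AMS} \;=\;
\frac{\;\mathrm{mut}_{TCW} / \mathrm{mut}_C\;}
     {\;\mathrm{ctx}_{TCW} / \mathrm{ctx}_C\;}
$$

where the numerator fractions count mutations in TCW motifs among all
eligible mutated C/G, and the context fractions count TCW plus WGA
motifs and C+G bases inside the 41-nucleotide window (`window = 20` each
side) centered on every eligible mutation. Windows overlap freely and
are summed with multiplicity — each mutation contributes its own window
— and are truncated, not discarded, at contig ends. A score of 1 means
mutated cytosines fall on TCW no more often than the local sequence
supplies TCW contexts; APOBEC-driven samples score well above 1.

Two eligibility conventions are exposed through `subs`: the default
`"ct_cg"` restricts to C>T and C>G changes (the classical definition of
APOBEC-type events), `"all"` admits any mutated C/G. Both are available
because published descriptions vary in whether C>A transversions are
admitted; the choice shifts absolute scores slightly but not rankings.

### A calibration subtlety in the background tally

Counting *every* C/G inside the window makes the context fraction a
biased estimate of the quantity the numerator measures. Two classes of
window positions can never be observed as motif centers: the outermost
base on each side (one flank falls outside the window) and the two bases
adjacent to the mutated center (their required T or W flank is the
mutated C/G itself, which is neither). Including them deflates the
context TCW fraction by roughly `41/39` and, because windows oversample
neighborhoods of mutated cytosines, by a further factor from the
center-adjacent positions — in simulation the null mean score lands near
1.05 rather than 1. `compute_ams()` therefore excludes those positions
from the C+G tally. The correction is a near-constant rescaling, so
correlations, rankings and dichotomizations are unaffected, but the
score becomes properly centered: mutations placed uniformly over
cytosines give a cohort mean AMS statistically indistinguishable from 1
(checked in the test suite at 200 samples).

## YTCA / RTCA motif attribution

Within TCW mutations the base at offset −2 separates enzyme preferences:
a pyrimidine (Y) is the A3A-like signature, a purine (R) the A3B-like
one. `ytca_rtca_counts()` reports per-sample and cohort counts of YTCA,
RTCA (3' base A) and the inclusive YTCW/RTCW classes, with their ratios.
A cohort dominated by A3A shows YTCA:RTCA well above 1 — on simulated
cohorts with the preceding-base pyrimidine probability planted at 0.7
the recovered ratio is 7:3, the regime reported for squamous cell
carcinomas of the esophagus and oral cavity.

## Signature activity refitting

Rather than de novo signature extraction (a matrix-factorization problem
with its own stability questions, deliberately out of scope), activities
are estimated by refitting: each sample's 96-channel counts are
decomposed against a user-supplied reference catalog by nonnegative
least squares on raw counts, so activities are interpretable as
estimated mutation counts per signature. Cohort-level pruning then
drops any signature holding less than `prune_frac` (default 1%) of total
activity and refits to a fixed point. Pruning at cohort rather than
per-sample level mirrors how signature repertoires are reported for a
cohort, and makes the retained set deterministic.

Two practical notes. First, NNLS lets spurious reference signatures
absorb Poisson noise; that absorption shrinks like the inverse square
root of the per-sample mutation count, so exact recovery of a planted
signature set needs reasonably deep catalogs (the test suite uses
500–1500 mutations per sample; at a few hundred per sample an extra
signature can linger just above 1%). Second, the least-squares objective
is on raw counts — no per-sample normalization — so high-burden samples
weigh more in the pruning shares, which matches their weight in the
cohort's mutation burden.

The shipped reference (`inst/extdata/signatures_8_synthetic.tsv`) is a
synthetic 8-signature catalog: two APOBEC analogs with their mass on the
TCW C>T and C>G channels plus six sparse random backgrounds. It is a
stand-in with APOBEC-like structure for tests and examples, not a copy
of any published reference set.

## Survival analysis

`optimal_cutoff()` dichotomizes a continuous score (typically AMS) at
the threshold minimizing the two-sided log-rank p-value. Candidates are
the midpoints between consecutive distinct score values whose induced
split leaves both groups with at least `minprop` (default 0.1) of the
cohort and at least two members; midpoints give the same search space as
a fixed-increment scan without an increment parameter, and ties in p are
broken toward the candidate nearest the median score, a deterministic
rule that prefers balanced splits. Because the minimum over many
correlated tests is anti-conservative — under a true null the minimum p
falls below 0.05 far more than 5% of the time, which the test suite
demonstrates rather than hides — a permutation-adjusted p-value
(`n_perm`) is provided: the observed minimum is referred to the null
distribution of minima over score permutations.

Group inference uses the standard machinery: `survival::survdiff` for
the log-rank test and `survival::coxph` with Efron tie handling for
covariate-adjusted hazard ratios (Wald 95% intervals). The group term is
releveled so the reported HR is high-vs-low; categorical covariates take
the first sorted level as reference unless `ref_levels` overrides, kept
explicit so hazard ratios are reproducible across runs.

`quantile_groups()` implements upper/lower-tail grouping with linear
interpolation (type 7, R's default) quantiles; boundary ties join the
extreme groups, and a score whose tails meet (e.g. constant) is an
error rather than a silent everything-in-both-tails grouping.

## Mutation-pathway enrichment

The two-stage procedure compares mutation placement between cohort
groups (e.g. high vs low AMS). Stage 1 screens each pathway by a
two-sided Fisher test of observed pathway vs non-pathway mutation counts
against a gene-count-proportional expectation over a stated gene
universe, keeping pathways with p < 0.05 and Benjamini–Hochberg FDR
< 0.25. The exact form of this screening null is a genuinely open design
point — the construction here (expected counts proportional to pathway
size in the universe) is one defensible choice, it is declared in the
output, and the universe is an explicit argument rather than an
assumption. Stage 2 then tests each surviving pathway's 2×2 table of
mutation counts, pathway vs elsewhere crossed with the two groups, again
by two-sided Fisher with BH adjustment across the candidates; odds
ratios are reported as `ad/bc`. The two stages are separate multiple-
testing families. Fisher p-values and the BH step-up are delegated to
`stats` and verified in the suite against exhaustive hypergeometric
enumeration and a hand-rolled step-up, respectively.

## Expression and single-cell scores

The cytolytic (CYT) score is the geometric mean of `PRF1` and `GZMA`
with a small pseudo-abundance (`offset = 0.01`) so zero-expression
samples remain finite; 0 is allowed when both genes are positive.
`score_correlated_genes()` ranks genes by Spearman correlation with a
per-sample score — Spearman is the package-wide convention for
continuous associations — optionally keeping only positive correlates
and truncating to `top_n` (e.g. the top 400 as GSEA input).
`geneset_score()` averages gene-wise z-scored log1p expression over a
set; plain z-scoring (affine-invariant) and raw means are also
available. Missing set genes warn by name rather than fail.

Single-cell helpers operate on annotated cell metadata. QC keeps cells
with 300–8000 detected genes, at most 20000 counts and at most 10%
mitochondrial reads, all bounds inclusive — the inclusive reading of
ranges like "300-8000" is a choice, stated here, and tallied per
criterion so filter behavior is auditable. Ro/e compares each cell
type's observed count per group to the chi-square expectation
`(row total × column total) / grand total`; ratios above 1 flag
enrichment, and the margins of observed and expected agree exactly by
construction. `refgene_signature()` ranks candidate genes by Spearman
correlation (on log1p counts) with a reference gene across cells, the
construction behind exhaustion- or regulation-style scores built around
a marker such as `HAVCR2` or `IL2RA`; cell-level scoring then goes
through `geneset_score()`. `downsample_cells()` performs seeded,
per-group uniform downsampling (default 1000 cells) for trajectory-style
analyses, keeping small groups whole.

## Synthetic cohorts and what they do (not) show

Every generator runs a single seeded stream (`withr::with_seed`) and
returns a truth bundle recording the seed and planted parameters;
identical seeds reproduce outputs byte-identically, and truth bundles
round-trip through YAML.

* `gen_reference()` draws i.i.d. bases at a stated GC fraction (defaults
  0.45, a genome-like value). It has no repeats, isochores, or
  chromatin — context frequencies are the only realistic feature.
* `gen_cohort_mutations()` draws per-signature counts (Poisson around
  expected activities, e.g. from `sample_activity_matrix()`), draws each
  mutation's channel from its signature profile, and places it uniformly
  among genome positions with the matching normalized trinucleotide;
  placement is exact by indexed sampling, and an unavailable context is
  an error. For the four TCW channels the preceding base is pyrimidine
  with probability `ytca_pyrimidine_prob`, planting the A3A/A3B balance.
* `gen_uniform_mutations()` is the motif-free null for score
  calibration.
* `gen_survival()` uses exponential event times with the hazard
  multiplied by `hr` above a planted score cutoff, independent
  exponential censoring tuned to a target fraction, and survival-
  independent covariates. Default baseline hazard 0.02 per month gives
  median survival around 35 months below the cutoff, an ESCC-like
  scale.
* `gen_bulk_expression()` is a Gaussian copula: target Spearman
  correlations with a score are hit through the bivariate-normal
  identity `r = 2 sin(πρ/6)`, then values are exponentiated onto a
  TPM-like scale. Only the rank structure is modeled.
* `gen_sc_cohort()` draws cell types multinomially per group, negative
  binomial counts with planted co-expression modules (a shared latent
  factor per module), and overwrites a stated fraction of QC metadata
  fields with violations. The count matrix is a scaled-down
  transcriptome (~10²–10³ genes); QC metadata is drawn at full-
  transcriptome scale, since real thresholds like "300 genes detected"
  are meaningless against a 120-gene matrix.

Passing recovery tests on these cohorts shows the estimators invert the
generative structure they assume — signature mixtures, threshold hazard
effects, rank-correlated expression, multinomial composition. It does
not show robustness to what the generators omit: mutation clustering
(kataegis), copy-number-confounded burden, batch effects, doublets,
ambient RNA, or non-proportional hazards.

## Problem sizes and numerical choices

The shipped tests run on deliberately small instances: 169 samples ×
~500 mutations for activity-share recovery, 10,000 planted APOBEC
mutations for the motif-ratio check, a 30-signature catalog with 8
generating signatures for pruning recovery, 200 samples for null AMS
calibration and cutpoint/Cox recovery, and 200 replicates for log-rank
null uniformity — sizes chosen so the whole suite runs in a couple of
minutes while keeping Monte Carlo error far from the tolerances.
Signature columns are accepted when they sum to 1 within 1e-3 and
renormalized; NNLS is deterministic; pruning always retains at least
one signature; undefined ratios (zero denominators) are `NA` or `Inf`
flags, never exceptions that abort a cohort run.

## Limitations

The package consumes called, annotated variants and annotated cell
metadata; it does no calling, liftover, clustering, pseudotime, or
enrichment-statistic internals (GSEA/GSVA/deconvolution are upstream or
downstream tools whose inputs this package prepares). The optimal-
cutpoint p-value is exploratory unless permutation-adjusted. AMS on very
few eligible mutations is noisy, and samples with zero eligible
mutations are flagged rather than scored.
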