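---
title: "Knowledge-based two-stage SNP screening with min-p permutation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based two-stage SNP screening with min-p permutation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbscreen)
```

## The problem this package addresses

Pharmacogenomic association studies relate germline variants to adverse
drug reactions in cohorts that are, by clinical necessity, small — often
one or two hundred patients. At genome-wide scale the multiple-testing
burden then destroys power: after any honest family-wise correction over
10^5 SNPs, nothing survives. `kbscreen` implements a combined discovery
procedure that attacks the problem from three sides at once:

1. **Knowledge-based pre-filtering (KB-SNP).** Only SNPs in genes
   annotated with a target set of Gene Ontology terms (for example,
   transporter activity and its relatives when the drug's toxicity is
   transport-mediated) enter the statistical analysis. This shrinks the
   family of tests by one to two orders of magnitude *before* any
   p-value is computed, on grounds external to the data.
2. **Two-stage screening by joint analysis.** A first screening stage
   tests every candidate SNP on a homogeneous subset of the cohort
   (patients on monotherapy) and keeps SNPs with Fisher p below a
   liberal threshold `alpha1`. The second stage retests only the
   survivors on the *full* cohort, which contains the subset. Joint
   analysis re-uses the first-stage patients and is more powerful than
   independent replication at equal total sample size.
3. **A min-p permutation correction over the whole procedure.** The
   selection-plus-testing pipeline is replayed on outcome labels
   shuffled across the full cohort; the smallest stage-2 p-value of each
   replay builds the null distribution against which the observed
   statistic is judged. Because the permutation replays *both* stages,
   the adjusted p-value accounts for the selection effect of stage 1 as
   well as the number of candidates.

Around this core the package provides the supporting statistics the
analysis needs: exact Hardy–Weinberg and minor-allele-frequency quality
control, odds ratios with Woolf intervals, Benjamini–Hochberg q-values
for the single-stage scan, tied-rank Spearman scans of clinical
covariates, and logistic-regression model comparison by AIC with ROC/AUC
summaries.

## Statistical components and their exact conventions

### Genetic models and Fisher's exact test

For one SNP with minor-allele dosage $g_i \in \{0,1,2\}$ and binary
outcome $y_i$, `build_contingency()` forms the 2×2 table $a,b,c,d$
(event/no-event × minor/major unit) under three models:

* **allele** — each patient contributes two chromosome units and $g_i$
  of them are minor; the table total is $2n$;
* **dominant** — one unit per patient, minor-bearing iff $g_i \ge 1$;
* **recessive** — one unit per patient, minor iff $g_i = 2$.

The allele model deliberately counts chromosomes rather than patients:
only a $2n$ margin is consistent with reporting all three models on the
same cohort, and it is the standard allelic test. Screening uses the
allele model by default (`screen_config(model = "allele")`).

`fisher_exact_two_sided()` computes the two-sided p-value by the
minimum-likelihood rule: with margins fixed, it sums hypergeometric
point probabilities of all tables no more probable than the observed
one. Floating-point ties are resolved with a relative tolerance of
1e-7 on the comparison — the convention base R's `fisher.test()` also
uses, so the two agree to numerical precision (the test suite checks
this, and separately checks agreement with a direct enumeration oracle
to 1e-10). A degenerate margin yields p = 1.

The odds ratio is $ad/bc$; with any zero cell the Haldane–Anscombe
correction adds 0.5 to every cell before both the OR and the Woolf
log-normal 95% interval $\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b +
1/c + 1/d})$. The correction is a display convention, not part of the
test.

### Quality control

`qc_filter()` removes SNPs with exact Hardy–Weinberg p < 0.2 or
MAF < 0.05 (both exclusions strict, so a SNP exactly at a threshold is
kept). The HWE test is the full conditional enumeration over
heterozygote counts given the sample size and minor-allele count, with
the same probability-ordering and 1e-7 tie conventions as the Fisher
test and no mid-p correction; a monomorphic SNP gets p = 1 and then
fails on MAF. The exact test is preferred to the chi-squared
approximation because post-filter counts can be small. QC runs on the
full dataset, which also fixes the minor-allele orientation used at
both screening stages — a single orientation avoids sign flips between
stages.

Missing data conventions: patients with a missing outcome grade are
dropped globally at `define_endpoint()`; patients with a missing
genotype are dropped per SNP (complete case per test); covariate
missingness is handled per model with a reported count.

### Two-stage screening and the permutation null

`run_two_stage()` computes stage-1 Fisher p-values on the monotherapy
rows, selects SNPs with $p < \alpha_1$ (default 0.005), recomputes p on
the full cohort for survivors only, and reports the smallest stage-2 p
(1.0 when nothing survives — the conservative convention that keeps the
null vector a fixed length).

`permutation_null()` repeats, `n_perm` times: shuffle the outcome
labels uniformly across *all* patients of the full cohort (the
monotherapy flag stays put, so the permuted first dataset is re-extracted
from the permuted full dataset), replay both stages, record the min
stage-2 p. Label shuffling is unstratified by default because outcome
exchangeability across the whole cohort is exactly what the screening
assumes; `stratified = TRUE` shuffles within the monotherapy and
combination strata separately for sensitivity analyses. The default
repetition number is 100,000; `occurrence_probability()` (below) is the
tool for judging whether a smaller number suffices.

`adjusted_p()` is the plain proportion of null minima at or below the
observed value, $k/N$ with no $+1$ correction. Consequently an adjusted
p of 0 is attainable and should be read as "< 1/n_perm". The pipeline
reports an adjusted p for *every* post-QC candidate (its full-dataset p
against the min-p null), not only for stage-1 survivors, so that
non-survivors display as 1.0 rather than disappearing.

Implementation note: under permutation only the event margin and the
per-SNP count of minor units among events change, so two-sided Fisher
p-values are served from per-margin lookup tables cached across
permutations. The suite verifies that this fast path equals a plain
per-SNP loop of scalar Fisher calls exactly. The permutation stream is
a single sequential RNG seeded once per call (`screen_config(seed=)`);
execution is single-threaded, so sequential draws already give
bit-reproducibility.

### Multiplicity for the single-stage scan

For the scan of all post-QC candidates on the full dataset only,
`bh_qvalues()` applies the Benjamini–Hochberg step-up (via
`stats::p.adjust`). The family size is the number of post-QC
candidates — not the number of stage-1 survivors — because the q-value
summarizes the single-stage analysis in which no stage-1 selection
occurred.

### Covariate scans

`covariate_scan()` correlates each clinical covariate with the endpoint
by Spearman's rank correlation with midranks on ties; the two-sided p
uses the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
degrees of freedom, which reproduces published cohort-table values to
printed precision (asserted in the acceptance tests). Covariates
constant in the chosen dataset — concomitant drugs within the
monotherapy subset, structurally — are reported NA. On binary×binary
data this Spearman coefficient equals the phi coefficient, a property
the suite checks.

### Model comparison

`compare_models()` fits one logistic regression per term set (the
intercept-only NULL model always included), with genotype coded
additively as 0/1/2 inside the binary-outcome model — the appropriate
reading of an "ordinal genotype" predictor when the outcome itself is
binary. AIC is $-2\ell + 2\,n_{par}$ with $n_{par}$ counting the
intercept. Fits use IRLS with relative tolerance 1e-10 and at most 100
iterations; any coefficient beyond ±15 on the logit scale raises a
quasi-separation flag and warning while the achieved likelihood is
retained (no Firth penalization — a flagged fit is a finding, not an
error, since a concomitant drug taken by only a handful of patients can
perfectly predict events). AUC uses the Mann–Whitney rank formulation
with ties counted 1/2; the reported operating point maximizes Youden's
J with ties broken toward higher sensitivity, and the full ROC curve is
always emitted so any other convention can be read off.

### Permutation-count validity

`occurrence_probability(n, k, p_B)` evaluates the binomial point
probability $\binom{n}{k} p_B^k (1-p_B)^{n-k}$ entirely in log space via
log-gamma. This matters: at $n = 10^5$ the relevant values sit around
$10^{-241}$, far below double-precision underflow, so only the log10
value is exact and the mantissa×10^exponent rendering
(`format_occurrence()`) is derived from it.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every stage is testable without patient-level
data:

* independent SNPs with dosage ~ Binomial(2, MAF), MAF uniform on
  [0.05, 0.5] — genotypes in Hardy–Weinberg proportions by
  construction;
* genic SNPs grouped into contiguous gene blocks, each gene annotated
  with 1–3 GO terms from a pool whose leading terms form the
  knowledge-filter target list (about 10% of SNPs are intergenic);
* a logistic phenotype: logit P(event) = baseline + Σ β_snp·dosage +
  Σ β_cov·covariate, with the intercept tuned so the marginal event
  rate is the configured value (default 36/168 ≈ 0.214, a typical
  grade ≥ 2 toxicity incidence);
* defaults of 168 patients with a nested monotherapy subset of 53,
  drawn independently of genotype and outcome — exactly the
  exchangeability the permutation scheme assumes;
* covariates emulating a chemotherapy cohort table: an ordinal 0/1/2
  genetic factor (probabilities 81/73/14 per 168), a standardized
  continuous age, and five concomitant-drug indicators (prevalences
  34, 68, 11, 4 and 2 per 168) that are structurally zero for
  monotherapy patients;
* genotype missingness 0.005 per call, applied after the phenotype
  draw (missingness is therefore non-informative);
* grades drawn consistently with the binary endpoint (events get grade
  2–4, non-events 0–1) so `define_endpoint()` at threshold 2 recovers
  the simulated outcome.

What the generator does **not** emulate: linkage disequilibrium
(SNPs are independent; the screening method nowhere models LD, and an
optional correlation mode was judged out of scope), population
stratification, differential or informative missingness, array-level
genotyping error, and grade-assignment ambiguity. Green tests on these
cohorts therefore demonstrate the *procedure's* correctness and
calibration under its own assumptions — not robustness to confounding
or LD, which real cohorts may add.

## Experiment sizes used by the test suite

The suite's heavier checks use sizes chosen to make their statistical
assertions sharp while staying desk-scale:

* **Family-wise calibration**: 100 independent null cohorts (168
  patients, 300 post-QC SNPs, `alpha1` 0.005, 500 permutations each,
  distinct seeds); the fraction of replicates with adjusted p ≤ 0.05
  must fall inside the exact binomial 99% interval around 0.05.
* **Parameter recovery**: 200 cohorts of n = 2,000 with one causal SNP
  (log-OR 1.0 at MAF 0.3); Wald 95% intervals must cover the truth at a
  rate inside the binomial 99% interval around 0.95.
* **Oracle sweeps**: the exact HWE test is compared to a brute-force
  enumeration oracle for *every* genotype count with n ≤ 50; Fisher
  p-values to a hypergeometric enumeration oracle on 220 random tables;
  BH to a quadratic-time step-up on vectors up to length 1,000.
* **Determinism**: the full pipeline, run twice from the same seed on
  identical inputs, must produce byte-identical report bundles (no
  timestamps appear in any output file for this reason).

## Known limitations

* The min-p adjusted p-value is reported per SNP against the same null
  distribution; with very few survivors it is conservative for all but
  the top SNP.
* The plain $k/N$ permutation proportion is slightly anti-conservative
  relative to the $(k+1)/(N+1)$ convention; at the default 100,000
  permutations the difference is at most 10^-5.
* In-sample AUC and operating points are optimistic; the package
  deliberately offers no cross-validation, matching its scope as a
  screening tool.
* The exact HWE and Fisher tests are conditional tests and inherit
  their discreteness; at small counts attained significance levels can
  sit well below nominal thresholds.
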