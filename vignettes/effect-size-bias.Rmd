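---
title: "Testing geographic bias in risk-allele effect sizes: methods and design"
author: "snpclines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing geographic bias in risk-allele effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the data

Multi-centre case-control studies of complex diseases such as systemic
lupus erythematosus (SLE) recruit cases and controls at many centres
("collections") spread over a geographic gradient. Two questions arise
once per-SNP association has been established:

1. **Effect-size bias** — do the risk alleles carry systematically
   larger odds ratios (OR) in one geographic subgroup than another?
2. **Frequency clines** — do risk-allele frequencies (RAF) change
   gradually along the main axis of population differentiation?

`snpclines` implements the full analysis battery for these questions,
plus a seeded synthetic-cohort generator so that every stage can be
validated against a known simulation truth.

The data substrate is a `GenotypeExperiment`, a thin
`SummarizedExperiment` with a single `dosage` assay (markers x samples).
Every cell counts copies of the marker's *counted allele*: the risk
allele for risk SNPs, the allele more common in Northern Europe for
ancestry-informative markers (AIMs). Dosages are 0/1/2, or 0/1 for
hemizygous (X-linked) males; `NA` is the missing sentinel — never 0,
which is a legitimate dosage. X-linked markers are admitted for risk
SNPs only, and all X-linked *association* tables are restricted to
females so that every subject in a table contributes two allele copies.
Genomic coordinates are not modelled: no stage of the analysis uses
positions.

## The population-axis (N/S) score

Collections are placed on the North-South axis with a composite of AIM
allele frequencies:

1. Orient every AIM to the Northern-common allele
   (`flipToCountedAllele`).
2. Quality control: within each collection, compare case and control
   AIM frequencies in 2x2 allele-count tables (1-df Pearson chi-squared,
   no continuity correction). A collection with any AIM differing at
   `aim_alpha` is excluded outright — an ancestry-mismatched collection
   would contaminate every downstream stage.
3. Prune redundant AIMs: pairwise genotypic r-squared (squared Pearson
   correlation of dosages — appropriate for unphased data) above a
   cutoff of 0.8 marks a redundant pair; the member with the smaller
   across-collection frequency range is dropped. In practice redundant
   pairs sit near r-squared 0.85 and independent ones below 0.03, so any
   cutoff well inside that gap selects identically.
4. Select the `k = 3` most *informative* AIMs. "Informative" is
   operationalised as the largest across-collection frequency range
   (max - min): it is scale-free and reproduces the published selection.
   Ties break lexicographically for determinism.
5. Min-max rescale each selected AIM across collections to 0-100% and
   average: the **N/S score**. A collection at the maximum on all AIMs
   scores 100, at the minimum 0; the score is invariant to any affine
   transformation applied uniformly to an AIM's frequencies.

Recomputing the score from the bundled published per-collection AIM
frequencies (`europeanCollections()`) reproduces the published score
column for all 15 retained collections to within 0.09 — the residual is
rounding of the printed inputs, which carry one decimal. Whether the
original computation used rounded or unrounded frequencies is not
stated; we use the table as printed.

## Stratified association

Case-control comparison is allele-based (each autosomal subject
contributes two allele copies), stratified by collection:

* **Fixed effect**: Mantel-Haenszel,
  `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with a 95% CI from
  the Robins-Breslow-Greenland (RBG) variance of `ln OR_MH` and the
  p-value from the 1-df Mantel-Haenszel chi-squared statistic without
  continuity correction. The original analysis does not state its CI
  method; RBG is the standard choice, valid under both sparse-data and
  large-stratum asymptotics.
* **Random effects**: DerSimonian-Laird (DL) moment estimator of the
  between-stratum variance tau-squared on per-stratum log ORs, weights
  `1/(v_i + tau2)`, Wald CI. When Cochran's `Q <= df` the result
  coincides with fixed-effect inverse-variance pooling.
* **Heterogeneity**: `I2 = max(0, (Q - df)/Q) x 100`, banded
  low/moderate/high above 25/50/75%.
* **Zero cells**: the MH sums tolerate sporadic zero cells natively (no
  correction). For quantities needing per-stratum log ORs (DL, Q, I2),
  a stratum containing any zero cell gets 0.5 added to every cell
  (Haldane-Anscombe); strata with a zero margin are dropped. Strata with
  no data at all are dropped with a warning.
* **HWE**: control genotype counts per collection are tested against
  Hardy-Weinberg proportions with a 1-df chi-squared (conventional at
  the ~100-subject collection sizes involved; monomorphic markers are
  flagged rather than tested).
* **Conditional independence** of two associated SNPs in the same locus
  is assessed by pooled additive-dosage logistic regression with
  collection indicator covariates and a 1-df likelihood-ratio test for
  the added SNP. A stratified conditional-likelihood variant would
  target the same within-collection adjustment; the indicator form was
  chosen because it is simple to verify against a brute-force likelihood
  scan, which the test suite does.

The test suite checks all of these against independent oracles:
plain-loop formula evaluation to a relative 1e-10 on randomized strata,
`stats::mantelhaen.test`, and `metafor::rma.mh` / `metafor::rma(method
= "DL")`.

## The effect-size-bias battery

With per-subgroup association in hand (`central` vs `southern`, the
partition being an *input* — the published analysis assigns by country
and then demonstrates insensitivity to the cut via the N/S score
correlations):

* **Direction test**: of `n` non-tied SNPs, `k` have the larger
  southern OR; the two-sided exact binomial p is
  `min(1, 2 min(P(X<=k), P(X>=k)))`, `X ~ Bin(n, 1/2)`. The 8-of-9
  worked example gives 0.039 to the printed precision. For 15 of 20 the
  exact enumeration gives 0.0414; the 0.019 printed for that
  configuration in the original report is not reproduced by any
  two-sided exact binomial and the implementation reports the exact
  value.
* **Geometric means**: `G_mean = exp(mean(ln OR))` per subgroup, with a
  paired two-sided Student t test on per-SNP log-OR differences. The
  published "±" accompanying G_mean is interpreted as a geometric SD
  factor `exp(sd(ln OR))`; the original definition is unstated.
* **Per-SNP interaction test**: z on the log-OR difference with summed
  variances — the conventional two-study interaction test.
* **Risk-allele sums**: per-subject sums of dosages over the battery.
  Missing dosages are imputed by their expectation, `2 x RAF` of the
  subject's collection controls (`1 x RAF` for X-linked males), which
  preserves group means at call rates near 99%; subjects missing over
  20% of the battery are excluded. Group contrasts use equal-variance
  Student t tests and normal-theory 95% CIs (the published CI method is
  unstated; normal theory is the default here).
* **GRS**: `sum(ln OR x dosage)` per subject, with the OR taken from
  the subject's own subgroup's Mantel-Haenszel estimate; subgroup means
  of patients compared by Student t test.
* **Axis correlations**: per-collection means against the N/S score use
  a weighted Pearson correlation (weighted moments, t transform with
  `n - 2` df). Weights default to collection sample size; the original
  weighting is unstated.

## Cline analysis

Controls only (they represent the general population). Per SNP: a 2x2
allele-count chi-squared between the pooled central and southern
controls; the weighted Pearson correlation `r_xy` of per-collection
control RAF with the N/S score; and a weighted least-squares regression
of RAF (%) on score/100, so the slope reads as percentage points per
full axis traverse. The original slope units are unstated; this scale
puts simulated and published magnitudes on comparable footing. SNPs
with constant frequency across collections are reported with slope 0
and a note rather than an undefined correlation.

## The synthetic-cohort generator

`simulationConfig()` describes collections at positions along a [0, 1]
axis; every marker's frequency is linearly interpolated between a
north (axis 0) and south (axis 1) endpoint — the simplest cline
consistent with the linear-regression treatment above. Controls are
drawn at Hardy-Weinberg proportions; cases by rejection sampling from
the population genotype distribution under the disease model, which is
exact under both models and fast at desk scale:

* **logistic** — case probability `expit(alpha + sum(beta_j g_j))`,
  `beta_j = ln OR` per allele (multiplicative, matching the
  allele-based analysis), intercept calibrated to the baseline
  prevalence at the mean genotype;
* **liability threshold** — Gaussian liability with allele effects
  `0.588 x ln OR` (the standard logit-to-probit scale factor, an
  approximation), unit residual, threshold set from the prevalence.
  This is the model matching the hypothesis that cases are more alike
  across subpopulations than controls are.

Baseline prevalence defaults to 1%. In the rare-disease regime the case
genotype distribution is essentially invariant to the prevalence, while
the rejection sampler accepts at about the prevalence rate, so 1% keeps
the generator exact and tractable; pushing it to a clinically literal
0.05% would multiply the sampling cost twentyfold without changing any
distributional property the tests measure.

`paperLikeConfig()` bundles the study-shaped default: the 15 retained
collections with their published sizes and female fractions, axis
positions `(100 - N/S score)/100`, six AIMs spanning the published
frequency ranges, and the 20-SNP battery with subgroup ORs splitting
the published combined OR so that the southern OR is larger at 15 of 20
SNPs (ratio 1.25 typically; 2.0 and 1.55 at the two SNPs reported
individually significant; 0.8 at the three-plus-one SNPs with the
central trend; 1.0 at the single tied SNP — the unnamed phase-1
central-trending SNP is taken to be *rs4963128*, an arbitrary choice
the publication does not pin down). Risk-SNP clines are anchored so a
straight line through the subgroup mean axis positions reproduces the
published central and southern control RAFs, with endpoints clamped to
[1, 99]% — the published per-SNP regression slopes are not used as
simulation truth because their units are unstated and they are
numerically inconsistent with the published subgroup RAF differences,
which do reproduce the published 0.8-allele control-control sum gap.
Injected missingness defaults to 0.88% (the published 99.12% call
rate).

What the generator deliberately does **not** emulate: linkage
disequilibrium between markers (the battery tags distinct loci and
AIM-SNP LD was reported below 0.05), non-linear clines, genotyping
batch effects, or case-control ancestry mismatch within a collection.
Passing simulation-based tests therefore demonstrates correctness of
the estimators and the qualitative reproducibility of the
bias-and-cline pattern under the stated conditions — not that real
genotypes would yield the published data-dependent magnitudes (those
require the original genotypes, which were never deposited).

Because simulated cases and controls share a collection's gene pool by
construction, AIM quality control applied to synthetic cohorts can only
ever exclude collections by type-I error; pipeline runs on synthetic
cohorts therefore use `aim_alpha = 0.001`, while the real-data default
stays at the conventional per-test 0.05 with no multiplicity
adjustment (which reproduces the published exclusion of exactly 2 of 17
collections).

## The pipeline

```{r pipeline-example}
library(snpclines)
cfg <- list(sim_config = paperLikeConfig(), seed = 42, out_dir = "out",
            thresholds = list(aim_alpha = 0.001))
res <- runPipeline(cfg)
```

Stages run in the published order — AIM QC, N/S scoring, combined
association (SNPs with combined p above the significance threshold drop
out of the battery; designated same-locus pairs are pruned by the
conditional test), per-subgroup association, bias battery, clines —
and write fixed-column TSV reports plus a JSON manifest recording every
exclusion and count. Reports are byte-identical across reruns with the
same configuration and seed; numbers are formatted to 6 significant
digits for diffability. The battery can be pinned with
`battery_override` for exact-replication runs, mirroring the fixed
20-SNP battery of the original analysis. `inst/scripts/snpclines.R` is
a thin command-line wrapper (`simulate`, `run`) over these functions.

## Numerical choices and test scales

Tolerances and scales used by the validation suite, chosen as desk-scale
versions of the study conditions:

* meta-analysis oracle equivalence: 120 randomized strata sets,
  relative 1e-10;
* estimator calibration: 500 replicates of 5 collections x 200/arm at
  OR 1.5 (logistic), asserting mean ln-OR bias under 0.02 and RBG
  coverage in [93%, 97%];
* cline recovery: 200 replicates of 15 collections x 200 controls,
  asserting 95%-CI coverage of the simulated slope at >= 90%;
* headline pattern: 100 seeded study-shaped runs, asserting the
  direction count k in [13, 17] in >= 80% of runs and a larger
  control-control than case-case allele-sum gap in expectation;
* null calibration: 100 seeded null runs (all ORs 1), asserting
  direction-test and interaction-test rejection near the nominal 5%
  (the exact binomial at n = 20 has discrete size 0.041).

## Known limitations

* The conditional-independence test is the indicator-adjusted logistic
  form, not stratified conditional likelihood; with ~15 strata of ~200
  subjects the two agree closely, but with many tiny strata the
  indicator form can over-fit.
* Expected-dosage imputation assumes missingness at random within
  collection x marker.
* The N/S score is a group-level instrument: the three AIMs carry far
  too little information for individual-level ancestry assignment, and
  no individual-level correction (principal components, mixed models)
  is attempted — by design, matching the method under study.
* The liability-threshold mapping `0.588 x ln OR` is approximate; the
  generator's realized ORs are therefore calibrated exactly only under
  the logistic model, which is what the estimator-recovery tests use.
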