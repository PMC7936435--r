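---
title: "Methods: expression-methylation-drug response screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-methylation-drug response screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

# The analysis

`methscreen` screens a cancer cell-line panel for associations between the
expression of genes affecting DNA methylation or demethylation (GMDs) and
(i) drug response, (ii) epigenome-wide DNA methylation, and (iii) drug
response mediated by methylation of GMD-associated targets. The unit of
inference everywhere is a Spearman rank correlation between two
per-sample quantities inside a stratum (pancancer, or one cancer category
with at least 10 lines), so every screen is invariant to monotone
transforms of its inputs — RPKM versus log-RPKM expression, or any
monotone recalibration of IC50, give identical results.

## Rank correlation and its p-value

For each (predictor, target) pair the samples missing in either vector
are deleted pairwise, both remaining vectors are ranked with average
ranks for ties, and the Pearson formula is applied to the ranks. The
p-value uses the large-sample t approximation,
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) degrees of freedom. At
panel scale (strata from 10 to several hundred lines, up to millions of
pairs) an exact permutation null is infeasible and the t approximation is
the standard choice; its behaviour at the stratum floor (n = 10) is
conservative relative to the strength cut |ρ| > 0.5 that accompanies
every significance rule. Pairs with fewer than `min_n` (default 10,
equal to the stratum eligibility floor) complete observations, or with a
constant ranked vector, are *skipped*: they carry `NA` statistics in the
output but still count toward their family's multiplicity (below).

## Family-wise error accounting

Two significance regimes coexist, deliberately:

* **Probe-level stage 1** uses fixed raw-p thresholds. The base value
  10⁻⁶ is an epigenome-wide single-predictor threshold for 450K-scale
  probe sets; dividing by the number of GMDs screened gives the
  pancancer cut (10⁻⁶/72 = 1.389 × 10⁻⁸ at the study default), and
  further dividing by the number of eligible categories gives the
  stratified cut (6.039 × 10⁻¹⁰ at 23 categories). `derive_probe_thresholds()`
  recomputes both from their factors and the pipeline asserts equality
  with the printed constants in study-default mode. The thresholds adapt
  when fewer GMDs or categories are configured, keeping the derivation
  rather than the constant.
* **Everything else** uses Benjamini–Hochberg step-up FDR over an
  *explicitly declared* family size: agents × GMDs for the direct
  screen, GMDs × regions for stage-1 regions, agents × targets for
  stage 2, multiplied by the category count for stratified records.
  `bh_adjust(p, test_count)` pads the family with implicit p = 1 tests
  whenever `test_count` exceeds the number of p-values actually
  computed, so skipped combinations are never silently dropped from the
  multiplicity burden. Declaring a family smaller than the record count
  is an error.

For stratified runs the declared family is the product × n_categories.
Whether the records of all categories are then adjusted as one pooled
family or per category is genuinely ambiguous as an interpretation of
"also accounting for the categories"; both are implemented behind
`fdr_scope = c("pooled", "per_stratum")` with identical test-count
accounting, and `pooled` is the default because it yields one coherent
record set per analysis. Raw p-values and coefficients are identical in
the two modes.

Stage 2 adjusts probe-level and region-level targets as two separate
families, mirroring the separate reporting of probe and region results;
a single merged family would couple the two target kinds' multiplicity
for no operational gain.

## Probe QC

Three rules, applied by `run_qc()` in a fixed order:

1. betas with detection p ≥ 10⁻³ are masked per entry (boundary
   inclusive);
2. probes whose *median* detection p across all samples is ≥ 10⁻⁶ are
   dropped entirely;
3. probes on the SNP-overlap mask list are dropped.

Medians in rule 2 are computed on the raw detection matrix — including
entries rule 1 masked — so rules 1 and 2 commute; this is a documented
package choice, not an inference about how any particular study ordered
them. Masked entries become explicit `NA`s (0 is a valid beta) and
propagate as pairwise-unavailable downstream; nothing is imputed, and no
beta value is ever modified — only masked or dropped. The SNP-drop count
is taken after the detection drop, so the two counts are disjoint and
the QC report's bookkeeping identity (output = input − detection − SNP)
holds by construction.

## Region averaging

Regions are identified by (gene symbol, region category) with the
six-category 450K vocabulary — TSS1500, TSS200, 5′UTR, 1st exon, body,
3′UTR — taken verbatim from the annotation's semicolon-paired lists; no
coordinate arithmetic is performed, so 0/1-based and strand conventions
are delegated to the annotation file. Malformed rows (unpaired lists,
unknown categories) are rejected loudly rather than guessed. A probe
with k distinct (gene, region) pairs contributes to all k regions; a
gene can therefore never yield a seventh region. The region value is
the unweighted arithmetic mean of non-missing constituent betas
(region-level summarisers also offer medians or trimmed means; plain
averaging is used here and stated as such), a one-probe region is valid,
and a region is `NA` for a sample only when all its probes are missing
there. The epigenome average is the per-sample mean beta over all
QC-surviving probes.

## Conditional regression

For candidates strongly associated (|ρ| > 0.5) with one agent's
response, `fit_conditional()` fits OLS of log10(IC50) on three mutation
indicators — BRAF V600E, any non-synonymous KRAS variant, any
non-synonymous NRAS variant — plus the candidate predictor, with
two-sided t-tests per coefficient. Three separate indicators (rather
than one combined RAS flag) preserve the distinct biology of the three
genes; "non-synonymous" means any protein-changing class. A flag
constant over the complete cases (common inside small strata) is dropped
with a warning and the model refit; with all flags dropped the fit
reduces exactly to the simple regression, which the tests assert to
1e-10. Predictor p-values are BH-adjusted over the candidate family;
flag p-values are reported unadjusted. No robust or sandwich errors are
used — plain OLS t-tests are what this analysis calls for.

# The synthetic panel generator

`generate_panel()` exists so every downstream stage is testable without
external data. Its central device is a latent-Gaussian copula: each
variable (expression, probe beta, log-IC50) is a strictly monotone map
of a standard-normal latent, and a planted effect with target Spearman
ρ* shares latents with coefficient \(r = 2\sin(\pi\rho^*/6)\) — the
inverse of the Gaussian-copula Spearman formula — so the realised rank
correlation concentrates on ρ* regardless of the monotone maps applied.
The ledger records the *realised* within-stratum ρ of every planted
effect, measured on the observable tables exactly as the screens see
them.

What the generator emulates:

* RPKM-like expression as exponentiated Gaussians (non-negative,
  right-skewed);
* beta-values in (0, 1) via a logistic squash of region-level latents,
  with bimodality by region category — upstream regions (TSS1500,
  TSS200, 5′UTR, 1st exon) skewed unmethylated, gene bodies skewed
  methylated — and within-region probe correlation through a shared
  region factor;
* detection-p failures at a configurable entry rate (values planted at
  ≥ 10⁻³), whole failing probes (median ≥ 10⁻⁶), and a SNP mask covering
  a configurable probe fraction;
* cis effects as negative correlation between a GMD's own upstream-region
  betas and its expression; trans effects against other genes' probes or
  regions; methylation→drug and expression→drug couplings; additive
  log-IC50 shifts in mutation-flagged lines (the `rho_target` field of a
  `mutation_drug` effect is that shift in units of the agent's response
  SD, since a rank correlation is not the natural parameter of a group
  shift); and epigenome-average coupling through a global methylation
  factor shared by all probes;
* dataset-of-origin suffixes on agent ids (`@GDSC`, `@CCLE`), so agents
  present in two source screens stay separate response variables.

What it does not emulate: raw array intensities, the 5-mC/5-hmC mixture
(indistinguishable on bisulfite arrays anyway), copy-number variation,
batch structure, or realistic linkage between SNP masking and genotype.
Passing tests on these panels therefore demonstrate the *statistical
machinery* — calibration under the null, recovery of planted effect
sizes, family accounting — not biological validity on any real panel.

Generator defaults are fixed once: panels of 120 lines in four
categories, 12 GMDs is typical of the focused screens the tests run,
three probes per region, ~1% detection failures, 5% SNP-masked probes,
5% missing drug responses. Panel sizes in the test-suite studies are
scaled roughly tenfold down from a 645-line, 450K-probe panel (60–600
lines, 300–1500 probes) so each study completes in seconds to a couple
of minutes; chain-recovery and conditional-discrimination studies use
n = 600 and n = 300 with 20 seeded replicates, and the type-I study uses
500 simulations. Probes participating in planted effects (and probes of
GMD genes) are excluded from the SNP mask and planted detection
failures, so ground truth remains observable after QC — a deliberate
generator property, stated here because it makes recovery rates cleaner
than they would be on real data, where QC can remove true signal.

One global integer seed feeds a hierarchical per-table stream (structure,
methylation, expression, mutations, drugs, detection, mask), which keeps
each table stable under changes to the other tables' sizes and makes
panel files byte-identical across runs of the same configuration.

# Numerical choices and degenerate inputs

* All thresholds printed with "≥" are inclusive at the boundary, exactly
  as stated (detection p = 10⁻³ masks; median = 10⁻⁶ drops).
* Threshold derivations are rounded to 4 significant digits before being
  compared with their printed forms.
* Region means and epigenome means are plain sums over doubles; the
  oracle-equivalence tests pin them to 1e-12, and Spearman/BH pinned to
  1e-12/1e-15 against brute-force reimplementations.
* `|ρ| = 1` maps to p = 0 (the t statistic is infinite); `n < 3` yields
  `NA`.
* Zero-variance predictors are an error in `fit_conditional()` and a
  skip in the screens; an all-`NA` sample in `epigenome_mean()` warns
  and yields `NA`.
* Export ordering is a fixed total order (adjusted p, then |ρ|
  descending, then predictor and target lexicographically); numeric
  columns are written with 17 significant digits so write→read→write
  cycles are byte-identical.
* Duplicate (agent, sample) response measurements are collapsed to their
  mean on load, with a message.

# Limitations

The screens are marginal rank correlations: no partial correlations, no
covariate adjustment (beyond the dedicated mutation-conditional module),
no Pearson mode. Stratified findings in categories near the 10-line
floor are dominated by the |ρ| cut rather than the p cut. The
two-stage design conditions stage 2 on stage-1 selection without
accounting for selection in stage-2 inference — it is a screening
procedure, not a joint test. EPIC-array manifests and CpG-island context
(shores/shelves) aggregation are out of scope.
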