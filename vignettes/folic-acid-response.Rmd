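---
title: "Methods: folic-acid response analysis on synthetic hyperhomocysteinemia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folic-acid response analysis on synthetic hyperhomocysteinemia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faresponse)
```

## Overview

`faresponse` implements a paired pre/post analysis of high-dose folic-acid
(FA) supplementation in hyperhomocysteinemia (HHC) patients. The pipeline has
five analytic stages — responder stratification, LINE-1 global methylation,
a filtered multi-tissue epigenetic clock, group-specific variant hotspots,
and mutation-burden/age-change association — plus a synthetic-cohort
generator that produces every input the stages consume. Patient-level data
of this kind are not publicly depositable, so the generator is a first-class
component: it plants known group structure, effect sizes and carrier counts,
and the tests check that each stage recovers exactly what was planted.

## Responder stratification

A patient is an FA *responder* when serum homocysteine (HCY) strictly
decreased between the two sampling points, and a *non-responder* when it
remained unchanged or increased; ties therefore fall to the non-responder
side. No tolerance band is applied around "unchanged": the definition is the
sign of the raw difference. Per-patient change of any paired biomarker is
summarized as the signed relative change `100 * (after - before) / before`,
which is undefined (an error) for a zero baseline.

Paired comparisons are gated on normality: the Shapiro–Wilk test is applied
to the paired *differences* (the quantity whose normality the paired t-test
actually assumes; applying it per arm would test the wrong thing), and with
`p >= alpha` (default `alpha = 0.05`) a paired Student t-test is used,
otherwise the Wilcoxon matched-pairs signed-rank test. Missing values are
removed pairwise per analysis. If every difference is zero the comparison is
degenerate and reported as `p = 1` with a warning rather than an error, so a
fully static stratum does not abort a batch run.

Correlations reported as plain *r* are computed as Pearson; Spearman rank
correlation is used only where rank methods are explicitly requested (the
burden–age association below). This follows the usual convention that an
unqualified *r* denotes the product–moment coefficient.

## LINE-1 methylation

The pyrosequencing assay quantifies three CpG positions of the LINE-1
consensus per sample; global methylation is their arithmetic mean. Full
precision is kept internally and rounding to one decimal happens only at the
reporting layer. For each sample fraction (cfDNA, granulocyte, mononuclear)
the stage runs the gated paired test on the three-CpG averages and on each
CpG separately, reports the group-level mean of *per-patient* relative
changes (not the relative change of group means — the formula is defined per
patient), and correlates HCY with the LINE-1 average within each response
group, pooling both timepoints. Per-CpG p-values are reported unadjusted,
matching per-position reporting conventions; `holm = TRUE` adds a
Holm-adjusted column across the three CpGs.

## The filtered epigenetic clock

Chronological age is mapped to the clock scale with the anchored piecewise
transform `F(age) = log((age + 1)/(adult_age + 1))` below the anchor and
`(age - adult_age)/(adult_age + 1)` above it, with `adult_age = 20` years by
default (configurable). The transform is continuous, strictly increasing and
exactly invertible; the round-trip is tested to 1e-9 over 0–120 years.

Training restricts the beta matrix to a CpG whitelist — the clock sites
shared across array platforms — and fits an elastic net of transformed age
on those betas (`glmnet`). The mixing parameter defaults to 0.5; the penalty
strength is chosen by 10-fold cross-validation with a fold assignment fixed
by the seed, or may be supplied directly. Two numerical details matter:

* glmnet's early-stopping rule along the penalty path (`fdev`) is disabled
  during training. On low-noise data the path otherwise stops while the
  penalty is still large, visibly biasing predictions; with the rule off,
  cross-validation is free to select an effectively unpenalized fit when the
  data support one.
* When a fixed penalty is requested, the model is fitted along a short
  decreasing path ending at that value, which is how coordinate descent
  reaches a fully converged single-penalty solution; this makes training
  invariant (to solver tolerance) under duplication of every sample.

Prediction is `inverse(F)(intercept + sum(w_i * beta_i))` over the whitelist;
rows outside the whitelist are ignored, and a missing whitelist CpG is an
error unless mean-imputation from the stored training means is requested.
The per-patient biological-age delta is the post-minus-baseline difference
of predictions on matched sample columns, and "decreasing biological age"
means a strictly negative delta.

The clock applied to the cohort is trained on a *reference panel*, not on
the study patients — mirroring how published clocks are trained on external
multi-tissue collections. In the synthetic pipeline that panel is simulated
from the same ground-truth beta model (200 samples, ages uniform on 20–90
by default). One known consequence of penalized training is worth stating:
shrinkage of the coefficients attenuates predicted deltas toward zero by
roughly 10–25% at the default noise level, so recovered group mean deltas
sit slightly inside the planted values. The acceptance checks use 3x
standard-error bands, which accommodate this attenuation without hiding it;
the per-seed attenuation is visible in the written `age_deltas.tsv` against
the generator's `cohort_truth.tsv`.

Model serialization is a flat TSV of `(cpg_id, coefficient, mean_beta)` under
two header lines (intercept, anchor age), written with 17 significant digits
so the round-trip is bit-exact.

## Variant hotspots

Variants arrive as a MAF-like TSV (1-based inclusive coordinates; the
tumor-centric column names are reinterpreted for germline calls, with
`Tumor_Sample_Barcode` as the patient id). The gene panel is a BED file
(0-based, half-open), and the two conventions are reconciled in exactly one
place: a variant at 1-based position `p` lies in `[start0, end0)` iff
`start0 < p <= end0`. SNV classes use the standard six pyrimidine-referenced
categories (a purine reference is complemented, so A>G reports as T>C).

The ClinVar-style split is *annotated vs unknown*, not benign vs pathogenic:
a variant is "classified" when its normalized `chrom:pos:ref:alt` key
appears in the annotation table with any non-empty clinical-significance
string, including "Uncertain significance". Both sets are retained and
written.

Carrier frequencies count each patient once per variant regardless of
zygosity or multiplicity, as percentages of the group size (two-decimal
display). The hotspot rule is dual-threshold with deliberate boundary
semantics: a variant is a *graph node* when it occurs in at least 50% of
non-responders, and is *highlighted* when it occurs in at least 70% of
non-responders and in strictly less than 50% of responders. The pathway
graph is bipartite — central pathway nodes against (gene, mutation) nodes
for every graph-node hotspot, one edge per pathway membership, with the
highlight flag carried on edges — and is exported as GraphML and DOT.
Mutation summaries (classification/type/SNV-class counts, per-gene and
per-patient totals, the gene-by-patient oncomatrix with the two-or-more
`Multi_Hit` rule) are computed natively; the top-gene list breaks count ties
lexicographically for determinism.

## Burden–age association

Per-gene mutation burden is the count of variant records per (patient,
gene), zero-filled over the panel, using *all* panel variants (classified
and unclassified). Within a response group, each gene's burden is tested
against the biological-age delta with a two-sided Spearman rank correlation
and summarized by the OLS line `delta = intercept + slope * count`. Genes
with constant burden in the group are skipped with a flag. Raw p-values are
the default significance column — matching the convention of reporting the
single-gene result uncorrected — but a Benjamini–Hochberg column is always
carried when two or more genes are tested.

## The synthetic-cohort generator

The generator's defaults are the study conditions the pipeline models:

* 21 responders, 22 non-responders (43 patients).
* HCY baseline 16.3 ± 4.8 µmol/L; post-supplementation 11 ± 2.9 in
  responders and 19.6 ± 3.7 in non-responders. Group membership is planted:
  the (before, after) pair is drawn jointly — with a within-patient
  correlation of 0.5 — and rejected until the planted sign of change holds.
  Joint rejection with a correlated pair keeps the conditioning distortion
  of the marginal means well under one standard error; per-patient
  distributions are Gaussian, an assumption the summary statistics alone
  cannot confirm. Note that a Gaussian baseline around 16.3 necessarily
  places some patients below the 15 µmol/L diagnostic cutoff; the printed
  mean ± SD is treated as authoritative over the cutoff.
* Folate 46.3 ± 40 to 81.4 ± 29.4 nmol/L, truncated at zero (the large
  baseline SD makes truncation shift that mean upward by several nmol/L —
  visible in the outputs and expected).
* cfDNA 9.0 ± 4.8 to 8.1 ± 4.9 ng/mL with a mean per-patient relative
  change of −3.3% and a +0.2375 correlation with baseline HCY. Matching the
  before/after means *and* the mean relative change simultaneously forces a
  negative correlation between baseline level and relative change; the
  generator derives that correlation in closed form from
  `rho = (mu_after - mu_before * (1 + mu_r)) / (sd_before * sd_r)` with the
  relative-change SD fixed at 0.2.
* LINE-1 baselines per fraction and CpG follow the published summary table;
  post-supplementation adds +1.5 (cfDNA), +0.2 (granulocyte) and +1.45
  (mononuclear) percentage points — a +1.9% relative change on the cfDNA and
  mononuclear baselines. Variance is split into a patient-level intercept
  (SD 2.2), per-CpG baseline noise (SD 2.0) and within-patient paired noise
  (SD 1.5). The within-patient SD is chosen so the +0.2-point granulocyte
  shift is usually *not* significant at n = 43 while the other two fractions
  are strongly significant, reproducing the qualitative pattern the stages
  must handle. In responders the patient intercept is drawn with a −0.37
  correlation to HCY, planting the negative HCY/LINE-1 association there.
* Biological-age deltas: responders N(−0.5, 8) years. Non-responder deltas
  are generated through the CCT3 burden model
  `delta = -9.214 + 0.394 * count + N(0, 5.48)` with counts negative
  binomial (mean 9.93, size 2.56, SD ≈ 7). These parameters are mutually
  consistent: they imply a mean delta of −5.3 years, about 80% of patients
  decreasing, and a burden–delta correlation of ≈ 0.45 — all three
  quantities the pipeline is asked to recover. The implied burden (≈ 10
  CCT3 mutations per non-responder) is what the regression line forces;
  it makes CCT3 the most mutated panel gene by raw count, which is accepted
  as a consequence of taking the regression at face value.
* Planted variants: the four group-specific hotspot mutations (HIF3A
  21/22 vs 1/21, TYMS and DNMT3A 18/22, PRMT3 16/22), the two common MTHFR
  polymorphisms at 14/21 vs 14/22 and 8/21 vs 9/22 (near-equal between
  groups, so they pass the graph-node rule without being highlighted on one
  side), and one MTRR variant in the same regime. Carrier sets are sampled
  but their sizes are exact, so frequency recovery is deterministic.
  Background variants (Poisson, mean 12 per patient) are scattered over the
  41-gene panel with classification frequencies dominated by missense, and
  40% of them receive an annotation entry.
* Methylation arrays: a ground-truth linear beta model over 354 CpG ids —
  308 whitelist sites of which 272 carry non-zero slopes (±0.005–0.02 beta
  per transformed-age unit), the rest flat, plus 46 non-whitelist pure-noise
  rows — with Gaussian beta-scale noise (SD 0.02) clipped to [0, 1]. A Beta
  distribution was deliberately not used: the clock is a linear model and at
  this noise scale the tail shape is immaterial, while Gaussian noise keeps
  the noiseless case exactly affine and therefore exactly checkable.

One user seed drives everything through fixed named streams (a documented
splitting scheme), so a fixed seed yields byte-identical datasets and adding
draws to one stage never perturbs another.

What the generator does *not* emulate: read-level sequencing, array IDATs or
normalization artifacts, bisulfite-conversion error, cell-composition
effects, linkage between variants, or non-Gaussian biomarker tails. Passing
tests therefore demonstrate that the statistical machinery recovers planted
structure under idealized noise — not that the pipeline is robust to the
measurement pathologies of real arrays or sequencers.

## Problem sizes and reproducibility

The shipped analyses use the 43-patient cohort, a 200-sample reference panel
for clock training, and 354 CpG rows; the test suite additionally uses
scaled-down clocks (about 40 CpGs) where full size adds nothing to the
property under test. The `analysis/` scripts run the stages in order from
`results/data`, and `scripts/acceptance.R --seed N --out results/acceptance.json`
re-runs the whole pipeline from scratch and writes the headline numbers of
every stage as JSON. Reported stochastic quantities (correlations, deltas)
vary across seeds exactly as their standard errors suggest; the planted
discrete structure (group sizes, carrier counts, hotspot calls) does not
vary at all.
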