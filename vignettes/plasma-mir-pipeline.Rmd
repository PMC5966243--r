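---
title: "Methods: a plasma circulating-miRNA biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a plasma circulating-miRNA biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmamir)
```

## The study design this package implements

Circulating microRNAs (miRs) are stable in plasma and measurable by
RT-qPCR, which makes them candidates for minimally invasive cancer
biomarkers. A common two-phase design, and the one `plasmamir`
implements end to end, is:

1. **Discovery.** Plasma RNA from patients with similar clinical
   characteristics is pooled (2-3 patients per pool) and profiled on a
   genome-wide miR microarray. After present/absent calls against the chip
   background, background subtraction and a global median normalization,
   candidate miRs are selected by a rank test between benign and malignant
   pools, by a fold-change rule for special strata (here BRCA1-mutation
   carriers), and from the literature.
2. **Validation.** The candidates, a set of stable reference miRs and two
   haemolysis markers are quantified by RT-qPCR in individual samples.
   After per-sample quality control, expression is normalized to the
   per-sample median of the quantified panel and tested per contrast with
   Mann-Whitney tests under Benjamini-Hochberg FDR control.

Unsupervised Ward/Euclidean clustering of the pooled discovery profiles
provides the exploratory view that motivated the BRCA1 stratum analyses.

## The Cq scale and the normalization model

A quantification cycle (Cq) is the PCR cycle at which fluorescence crosses
threshold; one cycle is one doubling, so Cq is a negative log2 abundance.
Undetected reactions (no amplification within the 40-cycle run) are stored
as *missing*, never as 40: the run length is a detection limit, and
imputing it would bias every per-sample median downstream. A switch
(`impute_undetected`) exists for users who want the opposite convention.

Relative expression is the median-of-panel delta-Cq
`value[s, m] = median(detected Cq of sample s over the normalizer set) - Cq[s, m]`,
in log2 units, positive when miR `m` is more abundant than the panel
midpoint. For a sample with its full normalizer set detected, the median
of its own relative values over that set is zero by construction (a
property the test suite asserts). Linear fold changes between groups are
`2^(mean_A - mean_B)` of relative expression — a ratio of geometric means
on the linear scale. A median-centering option exists because published
studies do not always state their estimator.

Two open choices were resolved as follows:

* **Normalizer set.** The default is *all* quantified assays of the table
  (the full 25-miR panel in the emulated design). A configurable
  `normalizer_set` supports the narrower candidates-only variant.
* **Undetected reactions in medians.** Excluded (not imputed), because the
  detection limit censors high Cq and any imputation constant would be
  arbitrary. Samples with under half of the normalizer set detected are
  flagged and dropped rather than normalized against a thin median.

### Self-normalization attenuation

Because the tested candidates are themselves members of the normalizer
panel, a genuine group shift in a candidate slightly drags the group's
panel median with it, attenuating estimated fold changes toward 1. With 2
shifted assays in a 25-assay panel the attenuation is small (a few percent
of the fold change) but real; it is a property of the published
normalization scheme, not of this implementation, and users comparing
recovered to injected fold changes in simulations should expect it.

## Quality control

* **Reference expression.** The per-sample median Cq of the detected
  reference assays must be at or below `reference_median_cq_max`
  (default 20 cycles). The cutoff direction follows the exclusion
  rationale "too low expression": poor RNA yield appears as *high* Cq.
  Samples whose references are all undetected fail.
* **Haemolysis.** Red-blood-cell lysis releases erythrocyte-enriched
  miR-451. The default score is the per-sample median Cq of the full
  quantified panel minus the miR-451 Cq (log2 units; higher = more
  miR-451 = more contamination), excluding strictly above 6.0. The
  classic two-marker delta `Cq(miR-23a) - Cq(miR-451)` is available via
  `haemolysis_denominator = "miR-23a"`. An undetected marker yields an
  undefined score and a manual-review flag rather than auto-exclusion.
  Both checks are evaluated independently per sample and reasons
  accumulate, so one sample's verdict never depends on another's.
* **Assay efficiency.** From a dilution series, the least-squares slope of
  Cq against log10 relative input gives the amplification efficiency
  `E = (10^(-1/slope) - 1) * 100`; a slope of -3.3219 cycles per 10-fold
  dilution is 100%. Assays pass inside 90-110% with r² >= 0.99 and a
  negative slope. The r² gate quantifies "linearly amplified"; 0.99 is the
  field convention and is configurable.

## Microarray processing choices

Present-calls use a strict inequality against
`background mean + 2 SD` (boundary spots are absent — conservative).
The global normalization median is taken over *all* background-subtracted
spots, floored at zero; a `median_over_present_only` switch covers the
alternative reading. The detection filter retains miRs present in at
least 20% of pooled groups, compared as an exact fraction (3/12 passes,
2/12 fails — no pre-rounding). The assay-range filter parses the numeric
miR designation from names like `hsa-miR-652-5p` and keeps numbers in
1-700 (where validated single-assay chemistry is expected); names without
a parseable number (the let-7 family) are kept and flagged rather than
silently dropped. Candidate-count caps (test-arm and fold-arm) are
configuration values, not constants, because they are properties of a
particular dataset.

## Statistics

* **Mann-Whitney U**: `U = #{a_i > b_j} + ties/2`. P-values are exact
  (permutation null) when both arms are at most `exact_max_n = 10` and
  tie-free; otherwise the tie-corrected normal approximation with
  continuity correction is used. Exactness is verified in the test suite
  against a full enumeration oracle for arm sizes up to 7.
* **Benjamini-Hochberg**: the step-up rule with rank critical values
  `i*q/m` at `q = 0.10`, reported alongside monotone adjusted p-values;
  the suite asserts the two formulations reject identically. The family
  is the set of candidate miRs tested within one contrast; subgroup
  analyses are separate families (the emulated study does not state its
  family definition, so the narrower, more conservative reading was
  chosen).
* **Spearman correlation** (age vs expression) with exact p for n <= 8;
  **Fisher's exact test** and its Freeman-Halton extension for 2x2 to 2x4
  tables, cross-checked against margin-fixed enumeration.
* Significance labels: `significant_raw` at two-sided alpha 0.05 and
  `significant_fdr` at BH q = 0.10, mirroring dual reporting conventions.

## Clustering

Ward's minimum-variance criterion on Euclidean distances, in the Ward.D2
convention (Lance-Williams updates on squared Euclidean distances), so a
merge height equals `sqrt(2 * delta-SS)` of that fusion and heights are
monotone. The test suite checks the merge sequence and heights against an
exhaustive oracle that evaluates every candidate merge's exact
within-cluster sum-of-squares increase. Tie-breaking among exactly equal
merge costs follows `stats::hclust`'s deterministic rule; the oracle
comparisons use continuous data where ties have probability zero. Newick
export places each node at half its merge height, so two leaves merged at
height `h` serialize as `(A:h/2,B:h/2);`.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws metadata (diagnosis, metastasis, BRCA1 and
familial status, age, T/N stage, receptor status) and Cq values under

```
cq[s, m] = baseline_cq[m] + sample_effect[s] - log2(FC[m, stratum(s)]) + noise
```

* Group effects act additively on Cq as `-log2(FC)`, which keeps injected
  fold changes exact on the linear scale and matches delta-Cq algebra.
  Reference miRs never receive effects.
* Defaults mirror the emulated validation design: 30 benign / 49 malignant
  samples (8 metastatic), 1 benign and 2 malignant BRCA1 carriers; the
  discovery helper uses 10 benign (3 carriers) / 19 malignant
  (6 metastatic, 2 carriers). `default_fold_changes()` injects the
  reported effect sizes (miR-652-5p 1.26-fold and let-7b 1.53-fold in
  malignant plasma, eight metastasis-associated shifts, and the two
  BRCA1-benign effects 2.16 and 0.25).
* Candidate baselines are drawn uniformly on [22, 32] cycles (plausible
  low-abundance plasma miRs); reference baselines on [15, 18] cycles,
  abundant enough that clean samples clear the 20-cycle reference gate.
  Both haemolysis markers are anchored at the median of the other
  baselines: in clean plasma they are typical mid-abundance panel members
  (the premise that makes a median-normalized miR-451 score meaningful),
  and since they carry no group effects they also pin the per-sample
  panel median, keeping the normalization reference group-stable.
* Per-reaction noise is a single global Gaussian (default SD 0.3 cycles);
  between-sample input variation is a global shift (SD 0.8 cycles) that
  normalization removes. Haemolysis subtracts 8 cycles from miR-451 in a
  configured fraction of samples; low RNA yield adds 8 cycles to every
  assay of a (disjoint) fraction, which is what makes reference-QC
  failures generable at all. Values beyond 40 cycles become undetected.
* Pooling averages linear-scale abundance,
  `cq_pool = -log2(mean(2^-cq))`, because mixing plasma mixes molecules,
  not cycles. Microarray intensities are `2^(40 - cq)` on top of additive
  Gaussian chip background, with a configurable fraction of miRs forced
  to background so present-calls have something to reject.
* Cohorts that are meant to be combined in one contrast (discovery plus
  validation BRCA1 carriers) must share `baseline_cq`; the realized
  baselines are exposed as an attribute for exactly this purpose.

Not emulated: assay-specific variance, RNA-isolation chemistry, chip
spot-level artifacts, batch effects, age- or stage-dependent expression,
and the heavy-tailed biological variance of real plasma miR levels. A
passing simulation therefore shows the pipeline's arithmetic and error
control are right under its stated model — not that the emulated study's
patient-level results would replicate.

## Problem sizes and runtime choices

The test suite runs replicate studies at the emulated design sizes
(30 vs 49 samples, 25-assay panel): 100 replicates for fold-change
recovery and haemolysis separation, 50 null replicates for FDR
calibration, 100 replicates of the 29-sample pooled discovery design for
the clustering pattern, and full enumeration oracles up to arm size 7
(Mann-Whitney), 6 points (Ward) and table totals of 12 (exact categorical
tests). These sizes keep the whole suite in the tens of seconds while
leaving the binomial error of the replicate counts small relative to the
asserted margins.

## Known limitations

* The haemolysis score in `panel_median` mode depends on the panel
  composition; panels dominated by disease-responsive miRs would shift
  clean-sample scores. The two-marker mode is the more portable fallback.
* geNorm M-values require a complete matrix; assays with missing values
  must be dropped or imputed first (the pipeline drops them before
  stability ranking). NormFinder's full ANOVA model is deliberately
  replaced by a transparent between/total variance-share score.
* Exact Mann-Whitney p-values are disabled in the presence of ties (the
  permutation distribution is no longer available in closed form);
  midranks with tie-corrected variance are used instead.
* `fisher.test` underlies the categorical tests; for 2x3 and 2x4 tables
  with large counts the exact enumeration grows quickly — the supported
  shapes match the baseline-table use case, not general r x c tables.
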