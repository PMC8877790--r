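---
title: "Statistical methods for larval zebrafish developmental-toxicity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for larval zebrafish developmental-toxicity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatox)
library(dplyr)
```

# Overview

`larvatox` implements the statistical backbone of a larval zebrafish
developmental-toxicity screen of endocrine-disrupting chemicals
(triclosan, triclocarban and 4-nonylphenol in the bundled registry):

1. **Photomotor-response QC** — a three-rule exclusion algorithm for
   per-larva locomotion traces recorded over alternating light/dark
   phases.
2. **Behavioral statistics** — one-way ANOVA with Tukey HSD on
   per-larva phase means, light and dark analyzed as separate families.
3. **Endpoint screening statistics** — per-endpoint chi-square across
   concentration groups with Bonferroni-corrected pairwise comparisons
   versus control, plus a 100%-mortality evaluability gate.
4. **DEG accounting** — the |log2FC| ≥ 0.75 & adjusted p < 0.1
   significance filter, count tables under two deduplication policies,
   and exact Venn decomposition of cross-chemical gene sets.
5. **Unit conversion** — nM ↔ µg/L via molar masses computed from
   molecular formulas.

A seeded synthetic-data generator produces all three input kinds
(traces, screening counts, per-gene DE tables) with known ground truth,
so every downstream stage is testable end to end without any external
data.

# The photomotor response assay and its QC

Larvae are assayed one per well over four 3-minute light-dark cycles
(24 min), movement integrated over 6-second bins: 8 phases × 30 bins =
240 bins, starting in light (`photoperiod_schedule()`). Healthy larvae
show scototaxis-driven hyperactivity in the dark; tracking artifacts and
non-responding larvae contaminate group means and must be removed before
any comparison.

`apply_qc()` evaluates three per-trace rules, always computing all three
flags (no short-circuit) and excluding a trace if any fires:

- **Light serial exceedance.** Within a trace, let V be its light-phase
  distances. The threshold is T = Q3(V) + 1.5 × IQR(V). The trace is
  excluded when 2 consecutive light bins, both past the 1:00 min mark of
  their phase, are each strictly above T. Skipping the first minute of
  each light phase avoids flagging the physiological startle burst at
  the dark→light transition.
- **Dark below light median.** Excluded when 2 consecutive dark bins are
  each strictly below the median of the trace's light-phase distances —
  a larva quieter in the dark than its own typical light movement is not
  exhibiting the expected response.
- **Light:dark ratio.** Excluded when mean(light)/mean(dark) ≥ 0.9
  (boundary inclusive): a non-responder. A zero dark mean is treated as
  a degenerate non-responder.

Interpretation decisions (the protocol statement leaves several details
open; these are this package's declared choices, all configurable
through `qc_thresholds()`):

- **Quantile population**: Q3/IQR and the light median are computed
  per-trace over that trace's own light bins, not pooled across larvae.
  This keeps each flag a pure function of its trace — which is also what
  makes QC idempotent and order-independent, two properties the test
  suite asserts.
- **Quantile convention**: linear interpolation between order statistics
  (R's type 7), the common scientific default; thresholds are echoed in
  the QC report so results are auditable.
- **"After the 1:00 min mark"** is read as within-phase elapsed time
  (end of bin) strictly greater than 60 s, i.e. the first 10 bins of
  each light phase are ineligible. The alternative reading (60 s of the
  whole session) would only ever affect the first phase.
- **"Two serial data points"** means exactly 2 consecutive bins with
  strict inequality in both; the run length is a parameter.
- **The ratio** is a ratio of phase means, not a mean of per-bin ratios
  (which would be undefined whenever a dark bin is zero).

Raising `ratio_cutoff` or `iqr_multiplier` can only shrink the excluded
set (monotonicity), and a trace's flags are invariant to the rest of the
cohort (locality); both are covered by property tests against brute-force
window enumeration.

# Behavioral statistics

The unit of analysis is the per-larva phase mean (`summarize_movement()`),
not the 6-s bin: bins within a larva are strongly dependent, and using
them directly would pseudo-replicate by a factor of ~120. Light and dark
means are analyzed as separate families with no cross-phase correction,
matching how such assays are conventionally reported.

`compare_groups()` fits a one-way ANOVA across all concentration groups
and follows with Tukey's HSD over all pairs, reported filtered to
treatment-versus-control contrasts with a hypo/hyper direction label.
Tukey (not Dunnett) is used deliberately: it is the procedure named in
the protocols this package follows. Shapiro–Wilk is computed on the
residuals as a diagnostic only — distance data are typically
right-skewed and non-normal, and the diagnostic is surfaced rather than
used to gate the ANOVA, which is robust at these group sizes (n = 24).
No non-parametric fallback is added, because adding one would change the
analysis being modeled.

# Endpoint screening statistics

Screening tables count affected/total embryos per endpoint ×
concentration × timepoint (24–120 hpf; n = 150 per condition).
`global_chi_square()` is an uncorrected Pearson chi-square on the 2 × k
table (Yates correction available as a flag but off by default — at
n = 150 per group the uncorrected test is standard); df = k − 1.
Expected counts below 5 warn but do not block. `pairwise_vs_control()`
runs 2 × 2 tests of each concentration against control with Bonferroni
adjustment, the family being the non-control comparisons within one
endpoint × duration × timepoint slice. The default analysis view is the
final, cumulative 120 hpf timepoint.

Denominator conventions: mortality is counted among all embryos;
abnormality endpoints among survivors at the screening timepoint (the
dead are not "not abnormal"); "total abnormalities" counts larvae with
at least one morphological abnormality, so a multiply-abnormal larva
counts once.

`mortality_gate()` marks a group non-evaluable only at exactly 100%
cumulative mortality by the final timepoint (149/150 dead is still
evaluable); gated groups are skipped by the behavior and abnormality
stages with an explicit report entry.

# DEG accounting

`filter_degs()` applies the significance filter with its boundary
semantics taken literally: |log2FC| ≥ 0.75 (inclusive) and adjusted
p < 0.1 (strict). Records with missing adjusted p (independent filtering
upstream) are never significant and are tallied separately as untested.

`count_by_condition()` implements two deduplication policies because
published count tables and prose summaries genuinely mix them: under
`"sum"`, duration totals add per-concentration counts and a gene
significant at two concentrations counts twice (count-table arithmetic);
under `"unique"`, each gene counts once and genes significant in
opposite directions at different concentrations are reported as
*variably regulated*. `"sum"` is the default for table-style output;
`"unique"` is what Venn inputs need.

`overlap_sets()` decomposes up to five named gene sets into exact,
disjoint Venn regions (membership by exact `gene_id` string match; alias
resolution is out of scope as database-version-dependent).
`combine_condition_sets()` builds the conventional cross-chemical
comparison: one set per chemical, unioned over all concentrations and
durations. `annotate_categories()` joins a user-supplied gene→category
map as a transparent stand-in for proprietary pathway tools.

# Unit conversion

µg/L = nM × molar mass (g/mol) × 10⁻³. Molar masses are computed from
molecular formulas with standard atomic weights rather than copied from
published converted values, because printed conversions in this
literature are occasionally inconsistent with the chemical's formula
mass — computing from the formula makes the registry self-validating
(the test suite checks every registry mass against independent hand
arithmetic). Conversions are displayed rounded to one decimal; full
precision is kept internally and the round-trip nM → µg/L → nM is exact
to 1e-12 relative tolerance.

```{r}
round(nM_to_ugL("triclocarban", 10), 1)
```

# The synthetic-data generator

The generator (`simulation_config()`, `simulate_traces()`,
`simulate_screening()`, `simulate_deg_table()`) emulates the study's
*statistical structure*, with group sizes as defaults: 24 larvae per
behavioral group, 150 embryos per screening condition, genome-scale
(20,000-gene) DE tables. One RNG stream per generator is derived from
the master seed, so adding a generator never perturbs another's draws;
identical configurations give bit-identical output.

**Traces.** Distance per bin is truncated-normal: normal on the bin
scale with mean = baseline × group multiplier and SD = `noise_cv` ×
mean, clipped at zero. Defaults: dark baseline 2.0 cm/bin, light 0.4
cm/bin, `noise_cv` 0.3 — chosen so that a healthy control larva shows
the expected several-fold dark:light contrast and is almost never
(≈0.2%) caught by the QC rules, which is what one expects of a QC step
meant to strip aberrant traces rather than decimate a cohort. Tracking
artifacts multiply a bin by `outlier_scale` with probability
`outlier_rate` per bin. Non-responders (probability `nonresponder_rate`
per larva) are created by rescaling the larva's *realized* light bins so
the realized light:dark mean ratio is exactly 0.95 — above the 0.9
cutoff by construction, which is why the ratio rule removes every
planted non-responder deterministically rather than merely usually.

**Screening.** Death occurs per 24-h interval with a baseline hazard
(cumulative; the dead stay dead); each abnormality endpoint is a
per-larva latent Bernoulli observed among survivors at every timepoint;
group effects act on the odds of each baseline probability. Hatching
dynamics are not modeled — "unhatched" is simulated like any other
latent endpoint.

**DE tables.** Null genes draw log2FC ~ N(0, 0.2) and raw p ~ U(0,1);
planted genes draw |log2FC| ~ N(2, 0.5) with random sign and raw
p ~ U(0, 10⁻⁶); adjusted p is Benjamini–Hochberg within each condition
(matching the "adjusted p" semantics of standard DE pipelines, whose
model fitting is out of scope). `shared_deg_counts` plants genes in
exactly the named chemical sets, disjointly from per-condition exclusive
plantings, so cross-chemical Venn regions are known by construction.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: bins are independent given phase (no
within-larva temporal autocorrelation, no habituation across cycles); no
plate or batch effects; expression effects are planted directly on the
log2FC/p scale rather than via a negative-binomial count model; and the
planted effect sizes are chosen to be detectable, so power numbers from
the simulation characterize the pipeline under its own assumptions, not
the assay's real-world sensitivity.

# Problem sizes and numerical choices

The test suite exercises the oracle-equivalence properties at reduced
scale (20-bin schedules, cohorts of 4–12 larvae, 200–1000 random tables
or sets per property) and the calibration checks at the study's group
sizes: the ANOVA type-I rate uses 1000 null replicates of 4 × 24 larvae;
hypoactivity detection uses 200 replicates of a control-plus-treated
design with a dark multiplier of 0.5; overlap recovery uses 5000-gene
tables with a planted-effect configuration (|log2FC| mean 2, SD 0.2, raw
p ≤ 10⁻⁶) under which the filter's recovery of planted genes is
essentially certain. These sizes are the package's validation design,
chosen to make Monte-Carlo error small relative to the properties being
asserted.

Ties and degenerate inputs: a constant light series gives IQR = 0 and
threshold T = the constant, which no bin strictly exceeds — the rule
correctly never fires on constant traces. Identical groups give F = 0,
p = 1. An all-zero margin makes the chi-square undefined and is an
error, distinct from the low-expected-count warning. Bonferroni caps at
1. Missing adjusted p never passes the DEG filter.

# Known limitations

- The QC quantile population (per-larva vs pooled) is a declared choice,
  not a reconstruction of any particular lab's scripts; per-larva is the
  default and the alternative would require pooling before flagging.
- `screening_tests()` analyzes one timepoint slice (default cumulative
  120 hpf); per-timepoint longitudinal modeling is out of scope.
- No dose-response modeling (BMD, probit) or trend tests; the screening
  statistics are the chi-square family described above.
- Gene identity is exact string match; no ortholog or alias mapping.
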