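---
title: "Methods: estimating and evaluating LDL cholesterol equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and evaluating LDL cholesterol equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Clinical laboratories report LDL cholesterol (LDL-C) from three measured
quantities — total cholesterol (TC), HDL-C and triglycerides (TG), all in
mg/dL — through the accounting identity

    LDL-C = TC − HDL-C − VLDL-C,

where VLDL-C is not measured but estimated. The Friedewald convention
estimates VLDL-C as TG/5, assuming a fixed TG:VLDL-C ratio of 5; in real
populations that ratio is heterogeneous and rises with TG, so Friedewald
increasingly underestimates VLDL-C's complement — LDL-C — in
hypertriglyceridemia and at low LDL-C, exactly where treatment decisions
are most sensitive. The estimators this package registers respond to that
problem in four structurally different ways: other fixed divisors, linear
regressions on the panel, a patient-specific divisor from a 2-D lookup
table (Martin/Hopkins), and quadratic/interaction forms (Sampson).

All estimation is done in mg/dL working units; equations originally
published in mmol/L would be converted to mg/dL-equivalent coefficients at
registry-build time (cholesterol × 38.67, TG × 88.57) — every packaged
entry is already expressed in mg/dL, recorded in the registry's
`source_units` column. Estimates are deliberately *not* rounded and *not*
clipped: a negative estimate is returned as-is and classifies to the
lowest guideline category, avoiding an undocumented clipping layer between
estimation and classification.

## Coefficient provenance

The registry (`inst/extdata/equations.tsv`) carries a `provenance` column.
Entries marked `transcribed` carry coefficients taken directly from the
original publications (Friedewald 1972; DeLong 1986; Hattori 1998;
Anandaraja 2005; Teerakanchana 2007; Ahmadi 2008; Puavilai 2009; Chen
2010; Vujovic 2010; de Cordova 2013; Martin 2013; Sampson 2020). For the
remaining equations the exact published coefficient sets could not be
verified against their sources when the registry was assembled; those
entries, marked `reconstructed`, are behavioural stand-ins calibrated so
that each equation's deviation from Friedewald at a median lipid profile
(TC 193, HDL-C 51, TG 114, LDL-C 114 mg/dL) reproduces that equation's
published median-error profile. Reconstructed entries are fit for
pipeline-level analyses (they have the right family, sign and magnitude of
bias) but should not be quoted as the authors' formulas; replacing them
with verified transcriptions only requires editing the registry file and
its recorded digest.

One transcription choice deserves a note: DeLong et al. (1986) is often
paraphrased as "divide TG by 6", but the published proposal is
VLDL-C = 0.16 × TG (divisor 6.25), which is what the registry uses; the
divisor-6 equation is Puavilai's.

## The adjustable-factor tables

The standard Martin/Hopkins table spans TG `[0, 400)` mg/dL in 29 strata
by 6 non-HDL-C strata (boundaries 100, 130, 160, 190, 220 mg/dL), with
factors from 3.1 (low TG, high non-HDL) to 9.5 (high TG, low non-HDL).
The published derivation's lowest TG stratum starts at 7 mg/dL; the
packaged table extends that stratum down to 0 so the strata tile the whole
domain. All strata are half-open `[low, high)` — a value exactly on a
boundary falls in the upper stratum, the same convention the guideline
category bins use — and non-HDL-C beyond the last boundary uses the last
stratum. The extended table covers TG `[400, 800)` as a single TG stratum
whose six factors (11.9 down to 6.7) are the high-TG stratum of the
original derivation table; the finer re-derived extended-TG table from the
later literature was not available for transcription, so the extended
variant should be read as the original derivation's high-TG row rather
than the re-derived surface.

Both tables ship as plain-text assets whose MD5 digests are recorded in
the package and asserted by the test suite, so silent edits are caught; a
transcription error that changed the extremes would additionally trip the
min = 3.1 / max = 9.5 test.

## Classification, error and reclassification conventions

- **Categories.** Eight half-open guideline bins with cut-points 40, 55,
  70, 100, 130, 160, 190 mg/dL; LDL-C of exactly 70 is "70–99"; negative
  estimates land in "<40".
- **Concordance.** The overall statistic is the fraction of pairs whose
  estimated and reference LDL-C share a category. Per-category breakdowns
  depend on which member of the pair defines the stratum; both
  orientations are implemented, reference-stratified being the default
  ("of patients whose measured LDL-C is in this category, how many were
  estimated correctly"), and every report names the orientation used.
  Overall concordance equals the denominator-weighted mean of either
  orientation's per-category values, which the tests assert.
- **Errors.** Signed error is estimate − reference (underestimation
  negative); relative error divides by the reference. Quantiles use linear
  interpolation between order statistics (R's default type 7) — immaterial
  at cohort sizes, decisive in 5-point fixtures, hence fixed and recorded.
  "Within tolerance" uses strict inequality `|error| < 5` mg/dL by
  default.
- **Reclassification.** Among records with Friedewald estimate below the
  cutpoint (default 70 mg/dL), the headline proportion counts those whose
  alternative estimate *and* reference are both at/above it. "Above the
  cutpoint" is implemented as `>= cutpoint` so the dichotomy partitions
  all values (a plain "<70 vs >70" reading leaves exactly-70 unassigned).
  Incorrect upward moves (alternative at/above, reference below) are
  counted and reported separately. An empty denominator yields a flagged
  undefined result rather than an exception, so callers keep the counts.
- **Strata.** Clinical thresholds follow their printed inequality
  directions exactly: kidney disease eGFR < 60 (strict), diabetes as
  diagnosis flag OR A1c > 6.5% (strict) OR fasting glucose ≥ 126 mg/dL
  (inclusive), inflammation hsCRP ≥ 2 mg/L (inclusive), thyroid
  dysfunction TSH < 0.5 or > 4.5 uIU/mL (both strict). Records missing a
  required covariate are excluded from that stratum and counted, never
  treated as negative. Records with unknown fasting status form their own
  stratum. Every stratified evaluation except the 400–799 mg/dL TG band
  is computed in the TG < 400 population, mirroring standard
  primary-analysis practice.

## The synthetic cohort generator

The generator exists so the pipeline can be exercised and calibrated
without patient data. Marginals for reference LDL-C, HDL-C, TG and Lp(a)-C
are log-normal, parameterised by median and IQR — the natural choice for
right-skewed lipid distributions when only quantiles are published.
`lognormal_params_from_quantiles()` sets the location to `log(median)`
(median exact by construction) and the scale to
`log(q75/q25) / (2·qnorm(0.75))`, the mean of the two one-sided scales;
when the published quantiles are not geometrically symmetric the IQR is
matched only approximately and the one-sided discrepancy is reported in
the returned `asymmetry` field (about 6% for the TG defaults).

Default calibration (changeable per `cohort_config()` argument): LDL-C
114 (90–141), HDL-C 51 (42–63), TG 114 (81–164), Lp(a)-C 6 (4–10) mg/dL;
TG:VLDL-C ratio 5.0 (4.4–5.9); 53.7% women; fasting status 19.4% / 11.9% /
68.7% (fasting / non-fasting / unknown); age bands 1.2% / 58.3% / 39.8% /
0.7% (<18, 18–59, ≥60, missing) with ages drawn within bands from a
normal(56, 16) truncated to the band; clinical-flag prevalences equal to
published subgroup counts over cohort size (e.g. ASCVD 32,223/4,939,528).
Laboratory covariates are drawn so the flag definitions hold exactly
(e.g. a diabetic record receives A1c in (6.6, 11)); flags are independent
of the lipids, a documented simplification.

The mechanism the analysis depends on — ratio heterogeneity coupled to
TG — is modelled by drawing the log-ratio with location
`log(5.0) + κ·(log TG − log 114)` and truncating to `[3, 13]` (keeping
VLDL-C physiologic and divisions stable; bounds are config-exposed). The
configured ratio median/IQR describe the *marginal* ratio distribution,
because that is what population tables print: the conditional noise scale
is derived as `sqrt(marginal variance − κ²·var(log TG))`, so the marginal
stays calibrated whatever the coupling, and a coupling too strong for the
configured marginal is rejected. The default κ = 0.35 is the log-TG
gradient of the adjustable-factor table at mid-range non-HDL-C
(`log(7.5/4.8)/log(346/99) ≈ 0.36`; an all-cells least-squares fit gives
0.31 and the per-column range is 0.25–0.39). Total cholesterol is emergent
— the exact sum LDL + HDL + VLDL + Lp(a) — so its median is only checked
softly (within 5% of 193 mg/dL) rather than calibrated.

A single RNG stream with an explicit seed drives all draws in a fixed
order; identical config and seed give a byte-identical cohort, and the
generator restores the caller's RNG state.

### What the generator does and does not emulate

It reproduces the published marginal distributions, covariate proportions,
the exact cholesterol accounting identity, and a TG-coupled ratio
heterogeneity strong enough that Friedewald's signed error is negatively
rank-correlated with TG among low-LDL records (asserted by a sign test in
the suite). It does **not** reproduce: joint lipid–comorbidity
correlations (flags are independent of lipids), fasting-dependent TG
shifts, non-HDL-C dependence of the TG:VLDL-C ratio (the coupling is to TG
only), or the bookkeeping of real ultracentrifugation references, which
fold Lp(a) cholesterol into reported LDL-C differently. Two consequences
matter when reading synthetic results:

1. Because the generator books Lp(a)-C outside the reference LDL-C while
   every closed-form estimator effectively estimates
   TC − HDL-C − VLDL-C, all equations inherit a positive offset of
   roughly the Lp(a)-C median (≈ 6 mg/dL) on synthetic cohorts.
2. That offset interacts with the TG mechanism: Friedewald's TG-driven
   underestimation partially cancels it at high TG, while the
   adjustable-factor estimator's better VLDL-C tracking preserves it.
   Cross-equation concordance *rankings* on synthetic data are therefore
   directional diagnostics of the machinery, not predictions of clinical
   rankings — on real data, where the reference absorbs Lp(a)-C, the
   adjustable-factor estimator's advantage is well documented.

## Numerical and interface choices

- Estimation never branches on units; the registry is the single source of
  coefficients, and the engine dispatches purely on the `family` column.
- Forcing an equation outside its TG validity domain requires an explicit
  `override_tg_domain = TRUE`; under the override, table-factor equations
  look the factor up in whichever table variant covers the TG value,
  clamping beyond 800 mg/dL to the nearest stratum.
- Human-readable reports round percentages and mg/dL errors to 0.1;
  machine-readable `summary.json` keeps full precision. Cohort CSVs are
  written with 17 significant digits so doubles round-trip exactly.
- Validation returns structured per-reason rejection counts
  (`missing_tc`, `missing_hdl`, `missing_tg`, `missing_ldl_ref`,
  `negative_value`, `tc_lt_hdl`); nothing is silently dropped, and each
  stratified output accounts for every input record as analysed, excluded
  or missing-covariate.

## Problem sizes

The test suite exercises unit properties on 200–10,000 random panels,
generator calibration on cohorts of 30,000 (module tests) and 100,000
(acceptance tests, matching medians within 1.5%), and the full 23-equation,
all-strata pipeline on 100,000 records, which completes in seconds on one
CPU. `scripts/acceptance.R` uses n = 100,000.

## Known limitations

Reconstructed coefficient sets (see provenance above) approximate, not
quote, their source equations. The extended-TG factor table is the
original derivation's high-TG row, not the finer re-derived surface. The
synthetic Lp(a) bookkeeping offset described above means absolute
concordance levels on synthetic cohorts sit below what the same machinery
reports on real data, and equation rankings can reorder around it. No
mmol/L user-facing mode, no alternative guideline bin schemes, and no
Bland–Altman plotting are provided in this version.
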