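---
title: "Methods: risk stratification for Group 4 medulloblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk stratification for Group 4 medulloblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `grp4risk`, in the order a cohort flows through the pipeline:
copy-number input to WCA calls, WCA calls to a prognostic signature,
signature plus clinical data to a risk scheme, and the survival
machinery that measures how well any of it works. It also describes
what the synthetic-cohort generator does and — just as importantly —
what it does not emulate.

## Whole-chromosome aberration calling

Input is arm-level: one row per (patient, chromosome, arm) with either a
categorical state or a mean log2 copy-number ratio, the natural boundary
when upstream processing is methylation-array segmentation. Calls follow
three conventions.

* **Thresholds.** An arm is gained at log2 ≥ +0.15 and lost at ≤ −0.15.
  The source analyses delegate this to array processing without printing
  thresholds, so the defaults here are a deliberately conservative,
  symmetric choice — wide enough to ignore noise and modest subclonal
  events, and configurable (`gain_thr`, `loss_thr`, in log2 units)
  wherever platform calibration differs.
* **Whole-chromosome concordance.** A whole-chromosome call requires
  every assessable arm to agree; a lone 16q loss stays an arm-level
  event and never enters the WCA counts. Acrocentric short arms (13p,
  14p, 15p, 21p, 22p) carry no assessable array content, so those
  chromosomes are called on the q arm alone. Sex chromosomes are
  excluded throughout; only autosomes 1–22 are modelled.
* **i17q precedence.** Isochromosome 17q (17p loss with 17q gain) is
  biologically exclusive of a whole-chromosome 17 gain and is treated as
  its own marker: when called, chromosome 17 is neutral and i17q is
  excluded from the gain/loss counts. A chromosome with no assessable
  arm is unassessable and excluded from counts; if that happens to
  chromosome 7, 8 or 11 the WCA class itself is unassessable rather
  than silently wrong.

The classifier is the fixed 2-of-3 rule: WCA-FR iff at least two of
{chr7 gain, chr8 loss, chr11 loss}, WCA-HR otherwise. Mosaic or
subclonal states have no representation here; an arm has exactly one
state after calling.

## Signature discovery

The search treats signature derivation as exact enumeration rather than
heuristic optimisation, which the problem size permits: after the 5%
cohort-frequency filter the candidate space is small (typically under
~20 (chromosome, direction) features), so every subset up to
`max_set_size` (default 5) crossed with every threshold k is scored.
A chromosome never appears with both directions in one rule.

**Scoring functional.** The original derivation reports an "optimum
combination ... for predicting PFS" without naming the objective. This
package ranks by smallest two-group log-rank p — the minimal notion of
PFS separation — with a documented tie-break cascade: larger c-index of
the (better-oriented) binary rule, then fewer features, then smaller k,
then rule string. The cascade makes the ranking a total order, so a
re-run on the same cohort is bit-identical. BH correction is applied
across all rules tested, treating the whole search as one family.

**Minimum support.** A rule whose positive (or negative) class is
nearly empty produces an asymptotic log-rank p-value that is not
trustworthy — a class of one or two patients can yield p ≈ 1e-14 by
chance and destroys false-discovery control over the rule space. The
candidate filter's own 5% frequency convention is therefore applied to
the rule classes as well (`min_support = 0.05`): under-supported rules
are kept in the output, flagged `degenerate` with null statistics, and
excluded from BH. The null-cohort simulation in the test suite (100
cohorts of n = 2000 with no survival effect) verifies that no
BH-significant rule appears in ≥95% of runs under this convention.

**Association structure.** Pairwise Fisher tests over WCA features
(including i17q) with Haldane-corrected odds ratios describe the
co-occurrence structure; hierarchical clustering uses average linkage
on d = (1 − φ)/2, φ being the Pearson correlation of the binary
features, so positively associated features cluster together. Constant
or sub-threshold features are excluded and reported.

## The three-tier risk scheme

`assign_grp4_risk()` encodes the scheme exactly as defined: favourable
= M0 and (WCA-FR or subgroup 7); very-high = M+ and WCA-HR; high = the
remainder. Missingness is handled by three-valued logic on the decision
actually reached: an M0 subgroup-7 patient is favourable even with an
unassessable WCA class (the subgroup alone decides), whereas an M0
WCA-HR patient with unknown subgroup is unclassifiable (subgroup 7
would change the label). The test suite enumerates all 20 complete-data
combinations against an independent reading of the rule text.

Comparator schemes are declarative config, not code: the clinical
dichotomy (high if M+ ∨ LCA ∨ MYC amp ∨ MYCN amp ∨ STR, else standard)
ships as a built-in, and two published molecular comparators ship as
editable plain-text reconstructions under `inst/extdata/schemes/` —
their exact operationalisation is not restated in the source text, so
the files are marked as reconstructions to be checked against the
original publications before use on real data.

**Reassignment convention.** When cross-tabulating the clinical scheme
against the three-tier scheme, a patient counts as reassigned unless
the (old, new) pair is in the equivalence map; the default map equates
clinical "high" with scheme "high" and nothing else. This is the only
convention under which the published flow fractions (standard-risk 37%
of the cohort, split 37/63 to favourable/high; high-risk 63%, split
9/31/60 to favourable/high/very-high) reproduce the published ~80%
reassignment, which `scripts/acceptance.R` recomputes.

## Survival machinery

Standard estimators are delegated to the `survival` package behind a
small stable surface; every wrapped estimator is cross-checked in the
test suite against an independent brute-force oracle (hand
product-limit computation, explicit O−E tables, pair enumeration for
the c-index, risk-set evaluation of the partial likelihood).

Numerical and procedural choices:

* **Ties.** Efron's approximation for tied event times (year-scale
  follow-up makes ties common); configurable to Breslow.
* **Convergence.** Cox fits iterate to a relative partial-likelihood
  change below 1e-9, capped at 100 iterations. Monotone likelihoods
  (e.g. a group with no events) are flagged rather than reported as
  estimates, so callers can fall back to a log-rank p-value.
* **Backwards selection.** Stay threshold 0.10 on the Wald p. A 0.05
  rule would be inconsistent with a final published model that retains
  p = 0.06 covariates; 0.10 is the smallest conventional threshold
  compatible with it. Complete-case analysis per model, with the
  per-model n reported.
* **Confidence intervals.** Log-log transform for KM intervals (bounded
  in [0, 1]); Wald intervals on the log-hazard scale for Cox.
* **PH diagnostics.** Scaled Schoenfeld residuals correlated against
  event-time rank (`transform = "rank"`), per covariate and globally;
  requires ≥3 events.
* **Optimism bootstrap.** Harrell's procedure: refit on each resample,
  optimism = mean(c-index on resample − c-index of that model on the
  original data), corrected = apparent − optimism. Resamples without
  events, or on which the model cannot be refitted, are redrawn and
  counted. Deterministic given the seed. The .632 variants were
  rejected for parsimony — "bias-corrected c-index with resampling" is
  the standard refit-on-resample procedure.
* **Scheme discrimination.** A scheme has no coefficients, so its
  c-index uses group-ordinal scores (favourable < high < very-high);
  the bootstrap then measures pure sampling optimism, which is near
  zero for a fixed rule — the machinery exists so schemes and fitted
  models are compared on the same footing.
* **Calibration.** Mean predicted survival at the horizon versus the
  KM estimate at the horizon per group; a group whose follow-up ends
  before the horizon (with survival still above zero) is an error, not
  a silent extrapolation. Horizon 0 degenerates to (1, 1) pairs.

## The synthetic-cohort generator

The generator exists so that every downstream stage has a testable
input with known truth. Each patient draws, in order: a methylation
subgroup (defaults 1/5/6/7/8 = 4/15/15/29/37%), per-chromosome
gain/loss states from a subgroup-conditional probability table, i17q
and an isolated 16q arm loss, metastatic stage (34% M+) and clinical
covariates, and finally a PFS time.

* **Aberration table defaults.** Highlighted published fractions are
  used where printed: chr11 loss 0.50 in subgroup 6 versus 0.08 in
  subgroup 7; chr13 loss 0.25 in subgroup 5; chr7 gain and chr8 loss
  strongly and near-equally enriched in subgroups 6 and 7; i17q 0.77 in
  subgroup 8 (and weighted to ≈56% cohort-wide); 16q arm loss 0.58 in
  subgroup 5. Everything else sits at a documented low baseline (0.05,
  or 0.15 in the cytogenetically complex subgroups 6 and 7). One known
  consequence: the implied cohort-wide WCA-FR share (~20%) undershoots
  the published 30%, because per-subgroup fractions are only printed
  for highlighted cells; the table is fully overridable in
  `cohort_config()`.
* **Survival model.** One-piece exponential per risk group: the rate is
  λ = −log(S₅)/5 with S₅ the configured 5-year PFS target for the
  patient's (post-hoc computable) risk group — defaults 0.97 / 0.67 /
  0.49 for favourable / high / very-high. Only 5-year targets are
  stated by the source; a constant hazard is the simplest model
  matching that constraint, and it makes the favourable-stratum KM at
  5 years checkable against the closed form exp(−5λ).
* **Censoring.** Uniform administrative censoring on (0, 2 × 6.6)
  years, matching the reported median follow-up of ≈6.6 years under the
  minimal standard assumption (only a median and IQR are reported).
* **Independence assumptions.** M-stage is drawn independently of
  subgroup (the source reports no significant association), and
  clinical covariates are mutually independent given the printed
  marginals. Missingness is off by default; when enabled it is
  missing-completely-at-random per variable — real cohort missingness
  is almost certainly informative, and no mechanism is reported to
  emulate.
* **Planted effects.** For signature-recovery studies the survival
  model can be switched to a planted rule: baseline S₅ = 0.6 with
  hazard multiplied by a configured ratio (0.3 in the recovery study;
  1.0 gives a null cohort) for rule-positive patients.

What passing tests on these cohorts shows: the pipeline's logic,
statistics and determinism are correct under the stated structure. What
it cannot show: behaviour under informative censoring, correlated
covariates, subclonal copy-number states, batch effects or subgroup
misclassification — none of which the generator emulates.

## Problem sizes and determinism

The simulation studies use: 20 planted cohorts of n = 2000 (hazard
ratio 0.3) for top-1 recovery; 100 null cohorts of n = 2000 for
false-discovery control; n = 10000 for marginal-frequency checks;
n = 5000 for the generator round-trip and calibration; 50 repetitions
for the Schoenfeld power/level checks; 20 meta-runs (40 bootstrap
rounds each, n = 60, 10 null covariates) for the optimism-direction
check. Scheme evaluation in the acceptance script uses 1000 bootstrap
rounds. All randomness flows from explicit seeds; regeneration with the
same config and seed is bit-identical, and provenance (config, seed,
package version, config hash) is written alongside every cohort.

## Known limitations

* Arm states are hard calls; no mosaic/subclonal representation.
* No time-varying covariates, competing risks, or overall-survival
  modelling — PFS is the only endpoint.
* Comparator scheme files are reconstructions, not transcriptions.
* The search's scoring functional is a documented choice; the original
  derivation's exact objective and candidate space are not restated in
  the source text.
* MYC/MYCN amplification enters as a clinical flag; no focal CNV
  calling is attempted.
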