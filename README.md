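# grp4risk

Molecular risk stratification for Group 4 medulloblastoma (MB_Grp4), the
largest molecular disease group of the commonest malignant childhood
brain tumour. MB_Grp4 lacks the single strong drivers of the WNT and SHH
groups; its clinically actionable structure lies in broad cytogenetics —
whole-chromosome aberrations (WCA) and isochromosome 17q — and in
DNA-methylation subgroups. `grp4risk` is a toolkit for analysts working
with such cohorts: it calls WCAs from arm-level copy number, re-derives
prognostic WCA signatures by exhaustive search, encodes a three-tier
risk scheme combining metastatic stage, WCA group and methylation
subgroup 7, and supplies the survival machinery (Kaplan–Meier, log-rank,
Cox PH, Harrell's c-index with bootstrap optimism correction,
calibration at a horizon) needed to validate and compare schemes. A
synthetic-cohort generator reproduces the clinical, cytogenetic and
survival structure the analysis assumes, so the entire pipeline is
testable without patient-level data.

## The core rules and statistics

**WCA calling.** An arm with mean log2 ratio ≥ +0.15 is gained, ≤ −0.15
lost (configurable). A chromosome is a whole-chromosome gain/loss when
all assessable arms agree (acrocentric chromosomes 13, 14, 15, 21, 22
are called on the q arm alone). Isochromosome 17q — 17p loss with 17q
gain — is a marker of its own: chromosome 17 is then called neutral and
i17q never enters the WCA counts.

**WCA-FR signature.** With S = [chr7 = gain] + [chr8 = loss] +
[chr11 = loss], a tumour is *WCA-FR* (favourable risk) iff S ≥ 2, else
*WCA-HR*. The signature-discovery module re-derives this rule from data:
it enumerates every k-of-set rule over candidate (chromosome, direction)
features with cohort frequency ≥ 5%, scores each by the two-group
log-rank statistic on progression-free survival (PFS), and ranks by
smallest p with documented tie-breaks (larger c-index, fewer features,
smaller k), applying Benjamini–Hochberg correction across the rule
space.

**Three-tier risk scheme.** With M-stage (M0/M+), WCA class and
methylation subgroup:

| risk group  | rule                                     |
|-------------|------------------------------------------|
| favourable  | M0 ∧ (WCA-FR ∨ subgroup 7)               |
| very high   | M+ ∧ WCA-HR                              |
| high        | the remainder (M+ ∧ WCA-FR; M0 ∧ WCA-HR ∧ ¬subgroup 7) |

Any field missing for the reached decision yields `unclassifiable`.

**Validation machinery.** Scheme discrimination is Harrell's c-index of
group-ordinal risk scores, bias-corrected by Harrell's optimism
bootstrap (refit on each resample, evaluate on the original data;
corrected = apparent − mean optimism). Calibration compares
model-predicted survival with Kaplan–Meier observed survival at a fixed
horizon (5 years) per risk group.

## Worked example

```r
library(grp4risk)

co <- generate_cohort(cohort_config(n_patients = 2000, seed = 7))
labels <- assign_grp4_risk(co$clinical$m_stage, co$wca$wca_class,
                           co$clinical$subgroup)
evaluate_scheme(labels, co$clinical$pfs_years, co$clinical$pfs_event,
                rounds = 200, seed = 7)
#> Scheme performance at 5 years:
#>        label   n events s_at_horizon lower upper
#> 1 favourable 504     22        0.959 0.934 0.975
#> 2       high 937    370        0.673 0.637 0.705
#> 3  very_high 559    311        0.499 0.452 0.545
#> log-rank chi2 = 340 (df 2), p = 1.24e-74
#> c-index: apparent 0.683, optimism 0.001 (200 rounds, 0 redrawn), bias-corrected 0.682
```

The three groups separate cleanly at 5 years (96% / 67% / 50% PFS,
matching the generator's configured targets of 97% / 67% / 49%), and the
ordinal scheme discriminates with a bias-corrected c-index of 0.68.

Re-deriving the signature on the same cohort:

```r
ranked <- search_signatures(wca_features(co$wca), co$clinical$pfs_years,
                            co$clinical$pfs_event, max_set_size = 3)
head(ranked[, c("rule", "n_positive", "logrank_p", "hazard_ratio")], 3)
#>            rule n_positive    logrank_p hazard_ratio
#> 1     7+,8-;k=1        868 6.198605e-20    0.4793788
#> 2 7+,8-,18+;k=1        948 1.227183e-19    0.4931529
#> 3 7+,8-,17+;k=1        901 3.152384e-19    0.4910699
```

Chromosome 7 gain / 8 loss combinations dominate the ranking, each with
a protective hazard ratio around 0.5. (This default cohort draws its
survival from the risk-group targets; when a ≥2-of-{7+, 8−, 11−} effect
is planted explicitly, the search recovers exactly that rule as top-1 —
see the methods vignette.)

A file-based pipeline is available through `write_cohort()` /
`read_cohort()` and the thin CLI at `inst/exec/grp4risk` (subcommands
`simulate`, `call-wca`, `discover-signature`, `stratify`, `evaluate`,
`compare-schemes`).

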