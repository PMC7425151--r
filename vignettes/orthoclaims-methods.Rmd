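---
title: "Methods: claims-based classification of elective orthopedic surgery indications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based classification of elective orthopedic surgery indications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclaims)
```

## The classification model

`orthoclaims` decides, for each surgical case, whether it represents one of
four elective procedure/primary-indication combinations — knee arthroplasty
for knee osteoarthritis (KOA), hip arthroplasty for hip osteoarthritis
(HOA), lumbar spinal surgery for spinal stenosis (SpS), or lumbar spinal
surgery for herniated disc (HD) — using nothing but the ICD-10 and CPT
codes billed for the patient in the claim window ending on the surgery
date.

The decision rule is deliberately simple and fully deterministic:

1. **Inclusion.** A combination *matches* when the window contains at least
   one of its inclusion CPT codes **and** at least one of its inclusion
   ICD-10 codes. A procedure code without a supporting diagnosis (or vice
   versa) is not evidence enough; such cases are labelled `other`. Each
   combination is only evaluated for cases operated by the matching surgeon
   specialty panel (spine vs hip/knee); `panel_restriction = FALSE` lifts
   this, which inflates apparent specificity because hip/knee surgeons are
   essentially never billed spine procedure codes.
2. **Spine tie-break.** The two spine combinations share most procedure
   codes, and stenosis and disc herniation frequently co-occur in coding.
   A case matching both is resolved by age at surgery: at or above the
   threshold (default 50 years) the case is SpS, below it HD. The
   tie-break runs after inclusion and before exclusion; with the default
   codebook the two spine exclusion lists are identical so the ordering is
   inconsequential, but the engine fixes it for custom codebooks.
3. **Exclusion.** A matched case whose window also contains a diagnosis
   from the combination's exclusion list — fractures, neoplasms,
   infections, incontinence and other signals of urgent, non-elective
   surgery — keeps the condition only as a *secondary* indication; the
   primary indication becomes `other`. Exclusions can only demote, never
   create, a match. Every fired pattern and the code that fired it is
   recorded for the misclassification audit.

The overall label is the unique combination left with `primary` status,
else `other`. A hip/knee window can in principle match both HOA and KOA
(hip and knee codes for one patient in one window); the model has no rule
to rank them, so the engine labels such a case `ambiguous` with a warning
rather than inventing a priority. This situation does not arise in the
synthetic archetypes and should be rare in practice.

### Code matching

ICD-10 is lexically hierarchical once display dots are removed: every
descendant of `M80` begins with the string `M80`. Normalization therefore
uppercases and strips dots (`M48.061` → `M48061`), and a hierarchical
pattern (written `M80*` in the codebook) is a plain string-prefix match.
Exact entries match only themselves. CPT codes are flat 5-character codes
and always match exactly.

Inclusion ICD-10 lists are exact-match by default. Some inclusion codes do
have ICD-10 children, and whether those children should count is a
genuinely open design question; the codebook flag `inclusion_hierarchy`
(default `FALSE`) extends prefix matching to inclusion lists without any
code change, and the default is simply the conservative reading that only
asterisked entries carry hierarchy semantics.

### The codebook is data

`inst/extdata/codebook.yaml` carries the four code lists, the panel
assignments, and the age threshold. `load_codebook()` validates it
(all four combinations present, no empty lists, panels consistent) and
`lint_codebook()` summarises it. Institutions with different billing
practices can edit the YAML without touching the engine; the round-trip
`write_codebook()`/`load_codebook()` is exact.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_days` | 90 | calendar days | closed span ending on (and including) the surgery date: `[surgery_date − 89, surgery_date]`. "90 days preceding surgery, inclusive of the surgery date" admits a 91-day reading; we take the 90-day span and leave the alternative one flag away. |
| `spine_age_threshold_years` | 50 | years | dual-coded spine cases resolve to SpS at or above, HD below |
| `inclusion_hierarchy` | `FALSE` | — | whether inclusion ICD-10 codes also match their children |
| `panel_restriction` | `TRUE` | — | evaluate each combination only on its panel's cases |
| `alpha` | 0.05 | — | two-sided level of the Clopper–Pearson intervals |
| eligibility | 21 / 40 | years | minimum age for spine / hip-knee cases in `filter_eligible()` |

## Validation statistics

Validation compares classifier output to gold-standard labels at two
levels: *indication* (the condition was among the indications; classifier
status `primary` or `secondary`) and *primary indication* (status
`primary` only). For each combination the evaluated set is the matching
panel's cases; counts partition that set, and

- sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), each with an exact
  Clopper–Pearson interval computed by beta-quantile inversion
  (`qbeta(α/2, x, n−x+1)` and `qbeta(1−α/2, x+1, n−x)`, with the endpoints
  pinned to 0 at x = 0 and 1 at x = n). The test suite checks this against
  an independent bisection on the binomial tail probabilities to 1e−8 for
  all x ≤ n ≤ 60, and checks ≥ 95% empirical coverage in seeded
  simulation — exact intervals are conservative by construction.
- predictive values follow Bayes' rule,
  `PPV(p) = Se·p / (Se·p + (1−Sp)(1−p))` and
  `NPV(p) = Sp(1−p) / (Sp(1−p) + (1−Se)p)`. A zero denominator (e.g. PPV
  at p = 0 under perfect specificity) is reported as `NaN` — undefined,
  not zero. PPV is nondecreasing and NPV nonincreasing in p.
- inter-rater agreement uses unweighted Cohen's kappa,
  `(p_o − p_e)/(1 − p_e)`; it is undefined (NaN, with a warning) when
  chance agreement is 1.
- a zero-denominator metric (no gold positives or no gold negatives for a
  combination in a given cohort) raises an error in the metric functions;
  the cohort-level wrapper `validate_cohort()` skips such rows with a
  message instead of reporting a silent 0.

`misclassification_report()` tags each false positive/negative with the
mechanical cause recoverable from the data alone: `exclusion_demotion:<pattern>`,
`tie_break_override`, `missing_cpt`, `missing_icd`, or `unresolved` for
errors that would require chart review to explain.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws cases from archetypes that mirror the observed
structure of a real validation cohort: the four clean elective archetypes,
dual-coded spine cases, and "other" surgeries whose codes never match.
The default mix (17% HOA, 15% KOA, 17% SpS of which ~30% dual-coded, 7%
HD, 44% other) mirrors the indication distribution of a consecutive
orthopedic case series, and uniform age ranges (e.g. 55–80 for the knee
archetype, 25–49 for clean HD, 30–70 for dual-coded gold-HD) are
consistent with the reported mean ages per indication (~62–67 for the
osteoarthritis/stenosis groups, ~52 for herniated disc) without matching
them exactly.

Corruptions are independent Bernoulli draws per case and reproduce the
documented real-world failure modes: `p_drop_cpt = 0.08` (procedure
billing codes missing from the extract), `p_drop_icd = 0.03`,
`p_add_exclusion = 0.05` (an osteonecrosis/fracture/incontinence-type
diagnosis contaminating an elective case and demoting it), and
`p_dual_spine_coding = 0.10`. Every case also receives a benign in-window
diagnosis and an exclusion diagnosis dated 100 days before surgery, so a
windowing bug would be observable. All randomness flows through the
config's single seed, the caller's RNG state is restored afterwards, and
identical configs give byte-identical tables.

Because the corruptions are recorded per case in the `truth` table, the
expected classification of every generated case is derivable from
archetype + corruption flags alone (`expected_classification()`), giving a
full-cohort oracle that never runs the engine. The test suite additionally
checks the engine against a deliberately naive nested-loop classifier on
250-case cohorts.

What the generator does **not** emulate: realistic billing-sequence
timing, surgeon identity, multi-surgery episodes, free-text notes, code
frequencies beyond one inclusion CPT/ICD pair per case, and gold-label
error (the synthetic gold labels are true by construction, whereas real
chart review has measurable inter-rater disagreement). Passing tests on
synthetic cohorts therefore demonstrates that the engine implements the
stated rules exactly and that the validation statistics recover planted
error rates — not that the code lists themselves are clinically complete
for any particular institution.

## Numerical and degenerate-input choices

- Dates are timezone-free ISO 8601 calendar dates throughout.
- Unparseable claim rows (unsupported system, malformed code, invalid
  date) are skipped, counted, and reported — administrative extracts are
  dirty, and a single bad row should not kill a run; a missing *column* is
  a schema error and fatal.
- Duplicate claim rows are retained; matching is set-semantic downstream.
- Duplicate `case_id`s are rejected (they would make the validation join
  ambiguous).
- An empty claim window is valid and classifies as `other`.
- Ages are taken as supplied (integer years at surgery); no birth-date
  arithmetic.
- Reported tables round to 2 decimals for display; machine-readable
  outputs carry full precision.

## Problem sizes

The test suite exercises cohorts of 40–1000 cases (oracle-equivalence at
250, parameter recovery at 20 replicates × 400 cases, windowing and
property checks on smaller fixtures) and 5000-replicate interval-coverage
simulations; the acceptance script uses a 790-case synthetic cohort.
These sizes give stable binomial checks at the planted rates while the
full suite runs in a few minutes on one CPU.

## Known limitations

- The spine age tie-break is a blunt instrument: a dual-coded gold-HD
  patient aged 50+ is systematically misclassified as SpS (and vice
  versa). This is inherent to the rule, is reproduced by the
  `dual_spine_*` archetypes, and is surfaced as `tie_break_override` in
  the audit. Stenosis and disc herniation are genuinely not mutually
  exclusive, so no coding rule can fully separate them.
- Exclusion patterns that are not site-specific (e.g. osteonecrosis
  `M87*`) can demote truly elective cases, which depresses primary-level
  sensitivity, most visibly for hip arthroplasty.
- Specificity depends on the composition of the evaluated panel (how many
  never-matching "other" cases it contains), so specificity values do not
  transfer across settings; the predictive-value curves over the prior
  probability are the portable summary.
- The classifier is binary per combination, not scored: no ROC/AUC
  machinery applies.
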