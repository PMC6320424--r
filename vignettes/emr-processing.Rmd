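---
title: "Processing administrative EMR data: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing administrative EMR data: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrforge)
```

This vignette documents the science behind `emrforge`: the procedures it
implements, the assumptions they rest on, the tunable parameters and their
defaults, the numerical decisions taken where the design was genuinely open,
and what the synthetic-data tests do and do not establish about real data.

## The problem

Administrative hospital EMR systems store data at the *record* level: one
table per domain (demographics, ward movements, bills, pharmacy
dispensings, diagnoses), each row a transaction. Three obstacles stand
between such an extract and a usable research cohort:

1. **Coding inconsistency over time.** Many systems migrated diagnosis
   coding mid-period (here: ICD-9-CM before a cut-over date, ICD-10-AM
   after). Longitudinal analyses need one nosology.
2. **No analysis-ready units.** Records must be aggregated to visits and
   visits to patients, with exclusion criteria applied at the right level
   and every dropped row accounted for.
3. **Missing constructs.** Disease complexity and socioeconomic status
   (SES) are rarely recorded; they must be derived from what is present
   (diagnosis codes, dispensings, postal codes, subsidy amounts) and the
   derived proxies must themselves be validated.

## Code standardization with fallback modification

New-era codes are backward-mapped into the older nosology. Backward rather
than forward mapping is the right direction when the newer nosology is more
granular and forms the smaller share of the data: many fine-grained new
codes collapse onto one old code, while the reverse mapping would be
one-to-many and ambiguous.

A code that fails direct crosswalk lookup undergoes *code modification*:

- **zero addition** — append one trailing `"0"`, then two, re-testing the
  crosswalk after each; rescues codes recorded at a coarser level than the
  crosswalk's keys;
- **truncation** — drop one trailing character at a time, re-testing at
  each length, down to a minimum of 3 characters (the category heading;
  letters count toward the 3, covering both ICD-10-style `A09` headings and
  ICD-9 V/E-codes); rescues codes recorded at a finer level than the keys.

The first hit wins; the method and (for truncation) the number of removed
characters are recorded per code. Codes unmapped after both fallbacks are
flagged and excluded downstream, but retained in the exclusion accounting.

Three decisions here were genuinely open:

- **Precedence.** Zero addition is attempted before truncation because it
  preserves all of the source code's recorded specificity, while truncation
  discards digits. The order is a switch (`prefer = "truncate_first"`), so
  sensitivity to the alternative precedence can be tested; on the shipped
  fixtures the two orders differ only for codes deliberately constructed to
  be reachable both ways.
- **Truncation granularity.** Truncation re-tests every intermediate length
  rather than jumping straight to 3 characters, so a 4-character key is
  preferred over its 3-character parent when both exist — the least
  destructive rescue wins.
- **One-to-many keys.** Backward maps can list several targets for one key.
  The first target in stored (file) order is returned, an ambiguity flag is
  set, and ambiguous matches are counted in the mapping statistics. This is
  deterministic and auditable; any smarter target choice would need
  clinical input the data cannot supply.

Whether a record is already in the target nosology is decided by its
`nosology` column when present, else by visit date against a configurable
cut-over date. Pass-through codes are normalized (periods stripped, case
folded up) but never modified, and never counted in conversion statistics.

Phenotyping applies the identical engine against a code-to-category
crosswalk in the style of the AHRQ single-level CCS file; each mapped code
receives exactly one category. No category count is hard-coded: the engine
is table-agnostic, and the shipped fixtures are toy tables (the real ACCD
and AHRQ files are licensed/versioned artifacts the package deliberately
does not ship).

Mapping statistics are reported per diagnosis role — primary (the
hospital's main diagnosis for the visit) versus secondary — on both code
instances and unique codes, with percentages on both the total and the
mapped denominator, because published mapping tables quote all four bases.

## The cohort cascade

Records aggregate within each of movement / billing / pharmacy by Visit ID
(sums for amounts, any() for flags, count-distinct for prescription drugs);
the three aggregates are **full-outer-joined** on Visit ID, so a visit seen
in any table exists. The diagnosis table is then filtered against this
visit universe (diagnoses on excluded or unknown visits never enter the
cohort), and the joined data link to demographics by Patient ID.

Exclusion rules run in a fixed, logged order:

| order | level | rule |
|---|---|---|
| 0 | visit | data quality: unresolvable dates or ages |
| 1 | visit | inpatient stay not fully inside the study window |
| 2 | visit | patient under the minimum age (default 21) at the visit |
| 3 | patient | no primary diagnosis |
| 4 | patient | birth year 1900 or earlier (the EMR's missing-birth-date sentinel) |
| 5 | patient | sex-implausible diagnosis (editable rule file) |

Each rule logs `n_before`, `n_removed`, `n_after`; the chain is exact and
re-running exclusions on filtered data removes zero rows. The window rule
targets inpatient visits only (it exists to guarantee complete episodes);
outpatient visits outside the window are untouched by it. Age at visit is
the floor of completed years between birth date and admission date — the
source system's convention is unknown, so the simplest auditable convention
is used. The sex-implausibility defaults cover pregnancy/childbirth and
female-infertility ranges for male patients and prostate/male-genital
ranges for female patients; the file is editable because published
descriptions give only examples.

Charges are inflation-adjusted to base-year levels per billing year
*before* aggregation to patient level, via a year → multiplier index table
(base-year multiplier 1 by convention). The observed period of a patient is
the span from first to last included visit, inclusive, in years.

## Derived measures

**CCI.** The 17-category Deyo ICD-9-CM adaptation with the original
Charlson weights (1/2/3/6), shipped as an editable CSV
(`category,prefixes,weight,supersedes`) so an updated weight scheme can be
swapped in. A category flags when any of the patient's codes (primary and
secondary, over all included visits) starts with any category prefix; the
hierarchy then keeps only the severe member of each pair (complicated
diabetes over uncomplicated, moderate/severe liver disease over mild,
metastatic solid tumour over non-metastatic malignancy). The index is the
weight sum — a non-negative integer, monotone in added comorbidities after
hierarchy resolution.

**PPS.** Visit-level: distinct prescription drug codes dispensed in the
visit, excluding non-prescription items and devices; distinctness is by
drug code only (no finer key exists). Patient-level: the maximum visit
score across included visits — a burden peak, not an average, so it never
decreases as visits accrue.

**Housing SES proxy.** Singapore postal codes identify individual blocks.
Public blocks resolve to the flat type with the largest proportion in the
block; an exact tie breaks toward the larger flat type (deterministic, and
conservative in the direction of higher SES). Flat types group by size:
rental/studio/1–2-room, 3-room, 4-room, 5-room/executive; private housing
comes from a separate postal list; postal codes on neither list resolve to
`missing` (non-residential or invalid addresses). Only the latest postal
code per patient is used — housing is assumed static over the window.

**Subsidy status and RSR.** A patient whose visits were all subsidized is
`subsidized`, all non-subsidized `nonsubsidized`, otherwise `mixed`. RSR is
the percentage of cumulative (inflation-adjusted) charges paid by
subsidies; it is undefined (missing, with a warning) for zero charges.

## The validation harness

Convergent and criterion validity of the proxies are assessed as:

- **Spearman correlations** (average ranks for ties, pairwise deletion) of
  CCI and PPS with each other and with utilization counts. CIs use the
  Fisher z-transform with standard error $1/\sqrt{n-3}$. "Holm adjustment
  of CIs" is ambiguous (Holm is a p-value procedure), so the step-down
  allocation is made explicit: the pair with the $k$-th smallest p-value
  gets a CI at level $1 - \alpha/(m-k+1)$ — never narrower than the
  unadjusted interval — and Holm-adjusted p-values are reported alongside,
  as are the unadjusted CIs.
- **Negative binomial GLMs** (log link) of each utilization count on CCI
  and on PPS, adjusting for sex, race, age and observed period; effects are
  $e^\beta$ with Wald 95% CIs. Dispersion is estimated by maximum
  likelihood; a diverging dispersion estimate (no overdispersion) falls
  back to Poisson with a warning, and non-convergence yields an explicit
  fit-failure row — never a silent result.
- **Multinomial logistic regression** of subsidy status (reference:
  nonsubsidized) and **linear regression** of RSR on housing group
  (reference: private), adjusting for nationality. An empty
  status-by-housing cell is reported with a warning; categories are never
  collapsed automatically, because collapsing changes the estimand.
- **Pearson chi-square** (housing × subsidy status; df $(r-1)(c-1)$, 8 for
  the 5 × 3 design) and **Kruskal–Wallis** (RSR across the 5 housing
  groups; tie-corrected, df 4). The degenerate all-tied case is defined as
  statistic 0 rather than the 0/0 the tie correction would produce.

Covariate coding (age continuous, race reference level by factor order) is
configurable through the inputs; defaults are the simplest choices.

## The synthetic-data generator

`generate_emr()` stands in for the hospital database. Its defaults are the
package's study conditions: 5000 patients, a 2005-01-01–2013-12-31 window,
coding cut-over 2010-01-01, charges restated to 2015 levels at 2.5%/year.
Disease complexity is a 3-tier latent variable (probabilities 0.6/0.3/0.1)
that jointly drives comorbidity code counts (Poisson means 0.2/1.2/3.5),
per-visit prescription counts (Poisson means 1/3/8) and visit counts per
class (negative binomial, e.g. inpatient means 0.2/0.8/2.5, dispersion
1.5) — the minimal structure under which convergent/criterion validity of
CCI and PPS should hold. The visit-count family matches the harness's model
family by design; this self-consistency is intentional and documented: the
recovery tests check the estimation machinery, not model robustness.

Housing groups follow a realistic distribution (about 3% smallest housing,
20% missing); subsidy propensity (0.85 down to 0.44) and subsidy depth
(0.65 down to 0.30) decrease with housing size, planting the
subsidy-status gradient and a monotone RSR gradient. 10% of new-era codes
are unmappable by construction, 15% mappable only through modification.
Rule violators (under-21 visits, out-of-window inpatient stays, birth-year
1900 patients, males with delivery codes, secondary-only patients) are
planted in ledger-recorded numbers, kept disjoint so each is removed by
exactly one rule. Regular patients are born 1925–1983 so the planted
under-21 visits are the only ones. The expected no-primary-diagnosis count
is computed in the ledger rather than fixed, because a patient whose only
primary diagnosis is an unmappable code legitimately falls to that rule
after unmapped-code exclusion.

The fixture crosswalks (~40 and ~42 keys) contain, by construction, codes
for every conversion route, one ambiguous multi-target key, and unmappable
codes; each code's route is recorded at construction, independently of the
engine, and the engine is additionally checked against a brute-force
candidate-enumeration oracle.

**What passing tests show — and don't.** The generator emulates table
structure, mixed-era coding, planted effect directions and exclusion
mechanics. It does not emulate real Singaporean epidemiology, billing
magnitudes, code frequency distributions, visit-date seasonality, or
informative missingness. Green tests establish that the machinery is
correct (exact accounting, exact planted-count recovery, nominal error
rates, CI coverage of planted effects); they say nothing about whether any
particular real EMR satisfies the assumptions above.

## Numerical choices and degenerate inputs

- Percentages are computed at full precision and rounded half-up to the
  printed precision (1–2 decimals) only in summaries.
- Monetary amounts are kept at full precision internally.
- Aggregation conservation (patient totals vs visit sums) is tested at
  1e-6 relative tolerance — pure floating-point summation noise.
- Empty inputs: empty diagnosis tables produce empty outputs with all-zero
  statistics; an empty pharmacy set gives PPS 0; an all-zero count outcome
  gives an explicit fit failure; a constant vector gives an
  undefined-correlation row without poisoning the other pairs; a zero
  margin in a contingency table is an error naming the empty row/column.
- Determinism: generation and the full pipeline are byte-identical given
  the seed; manifests of two same-seed runs differ only in timestamps.

## Problem sizes used in the test suite

Unit tests run on hand-checkable fixtures (2–10 rows) and 150–800-patient
synthetic cohorts. The end-to-end acceptance checks run the generator's
default 5000-patient conditions once (shared across checks), 100-replicate
CI-coverage simulations at n = 2000 (count effect 1.5) and n = 20000
(subsidy odds ratio 14, RSR offset +19 points), and 200 null simulations at
n = 1000 for the type-I error of the exposure test. These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping the
default suite in the low minutes.

## Known limitations

- The engine returns the first target of an ambiguous key; a clinically
  informed choice among targets is out of scope.
- No record de-duplication beyond exact key matches; conflicting movement
  rows for one visit are an error, not a merge.
- The DRG (diagnosis-related group) table of the source architecture is
  not modeled — its information is a subset of the diagnosis table.
- Housing is static (latest postal code only) and the housing → SES link
  is specific to settings with tiered public housing; elsewhere the proxy
  needs re-validation.
- The physicians' manual rating of modified codes is a human process; only
  its rate arithmetic (`validity_summary()`) is implemented.
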