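---
title: "Scoring antenatal care: the CTP tool and the APNCU index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring antenatal care: the CTP tool and the APNCU index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carescore)
```

## The problem

Health-services research on antenatal (prenatal) care has long scored
"adequacy" by counting visits. The most widely used instrument, the
APNCU index (Adequacy of Prenatal Care Utilization, Kotelchuck),
combines the month care began with the ratio of attended to recommended
visits — but it is blind to what happened at those visits. A woman who
attends twelve consultations at which nothing recommended is done scores
as well as one who receives the full basic package. The CTP tool
(Content and Timing of care in Pregnancy) addresses this by scoring
three content indicators with broad cross-guideline support — ultrasound
scans (US), blood-pressure measurements (BP) and blood screenings (BS) —
against minimum counts and against the trimesters in which guidelines
recommend they occur.

`carescore` implements both instruments over a common visit-level data
model, a calibrated synthetic-cohort simulator, and the
cross-tabulation/chi-square machinery used to compare them.

## Data model

One row per visit: `woman_id`, `gestational_week` (completed weeks,
0–45), `us`/`bp`/`bs` (non-negative counts of each intervention at that
visit; two BP measurements in one visit count twice), `ga_at_delivery`
(completed weeks, repeated per row and validated for consistency), and
an optional carried `scheduled` flag. Initiation of care is the minimum
visit week. Gestational age is kept in completed weeks throughout;
calendar-date arithmetic is assumed to have happened upstream.
Trajectories with zero visits are rejected with a distinct
undefined-initiation error rather than classified: a no-care group is a
substantively different population that the classifiers do not cover.

## The CTP decision sequence

Classification is a fixed four-step sequence; exactly one branch fires:

1. **Late initiation.** First visit after 14 completed weeks (week 14
   itself is timely — "completed weeks" reading) → *Inadequate*.
2. **Under-provision without over-provision.** Some whole-pregnancy
   count below its lower range (defaults US ≥ 2, BP ≥ 6, BS ≥ 2) while
   no count is above its upper range → *Inadequate*.
3. **Under-provision with over-provision.** Some count below its lower
   range while another exceeds its upper range (strictly above; a count
   equal to the upper value does not "exceed" it) → *Intermediate*.
4. **Timing check.** All lower ranges met: *Appropriate* when every
   per-trimester minimum is satisfied (T1 ≥ 1 US + 1 BP + 1 BS,
   T2 ≥ 1 US + 2 BP, T3 ≥ 3 BP + 1 BS), otherwise *Sufficient*. A
   single failed timing minimum demotes to Sufficient: Appropriate is
   defined by the timing of *all* basic interventions being as
   recommended. Exceeding an upper range once all minima are met has no
   effect — the tool deliberately carries no over-use penalty.

Two boundary conventions deserve note. Trimester boundaries are not
standardised in the source guidelines; the defaults here end T1 at 14
completed weeks (consistent with the initiation cutoff) and T2 at 28,
both configurable via `trimester_boundaries()`. Upper ranges are
likewise not published values: the shipped defaults (US 7, BP 10,
BS 10) sit in the neighbourhood of observed 75th percentiles of
national use and make the canonical over-provision example (8
ultrasounds) exceed its range; substantive analyses should set them
explicitly from their own national data. A timely initiator with zero
recorded interventions falls through step 2 to Inadequate.

Every result carries a `rule_trace` recording which node fired, so a
label can always be audited back to the counts that produced it.

## The APNCU index

Observed visits are the number of visit rows, regardless of content.
Expected visits are the recommended-schedule weeks falling between
initiation and delivery, floored at 1 (the initiation visit itself is
always expected, which also keeps the ratio defined for very early
deliveries). Categories: initiation after the 4th month *or* ratio
< 0.50 → *Inadequate*; then, with timely initiation, [0.50, 0.80) →
*Intermediate*, [0.80, 1.10) → *Adequate*, ≥ 1.10 → *AdequatePlus*.
The verbal definitions ("80–109%", "more than 110%") leave exactly
110% unassigned; the standard convention assigns it to AdequatePlus,
making the bands a partition of [0, ∞).

Months are mapped to weeks as "within the 4th month" ⇔ initiation at
or before 17 completed weeks (4 × 4.345 ≈ 17.4); the cutoff is
configurable. Expected counting from the exact initiation week is the
default; `expected_basis = "month"` reproduces the original
month-resolution convention by backing up to the first week of the
initiation month.

Two schedules ship with the package. `"acog"` encodes the classical
low-risk rhythm (4-weekly to 28, 2–3-weekly to 36, weekly to 42).
`"belgian"` is a 10-visit template to week 40 emulating the Belgian
low-risk guideline under which the tool was developed — using it
nullifies the ACOG/Belgian discrepancy in recommended visit numbers.
The authoritative Belgian week list is not published in machine form,
so the template weeks are a package choice; replications should pass
their own `visit_weeks`.

## The synthetic cohort simulator

No visit-level antenatal dataset of this kind is publicly deposited, so
the package generates its own. The `study_like` defaults are calibrated
to the development cohort's published care characteristics: initiation
median 7 weeks (IQR 6–10), 11 consultations (IQR 10–14), delivery at 40
weeks (IQR 38–40). Only medians and quartiles are published, so the
families are simulator choices: initiation and visit counts are floored
log-normals fitted to the quartiles (meanlog/sdlog 2.047/0.379 and
2.471/0.249), delivery a floored normal (mean 40.2, sd 1.5) truncated
to [22, 43]. Visit weeks are placed on an even grid from initiation to
delivery with ±1 week jitter; interventions are Bernoulli per visit
with per-trimester probabilities chosen so that whole-pregnancy totals
land near the published medians (≈5 US, ≈8 BP, ≈8 BS). One published
inconsistency is worth flagging: the blood-screening mean is printed as
4.6 against a median of 8 (6–10); the simulator follows the medians.

What the simulator does *not* emulate: provider switching,
sociodemographic structure, missing-diary behaviour, or the empirical
joint distribution of content and visit frequency. Passing calibration
tests therefore shows that the classifiers and comparison arithmetic
behave correctly on realistically shaped data — not that the simulator
reproduces the real cohort's category mix. The exact published CTP
marginals (10.2/8.4/36/45.3%) depend on the real data and are
deliberately not a simulation target; they are reproduced instead from
the published cross-tabulation, where they are pure arithmetic.

Presets: `all_appropriate` uses a deterministic textbook plan (2 US,
6 BP, 2 BS timed to satisfy every trimester minimum exactly);
`late_initiators` fixes initiation at week 20, past both instruments'
cutoffs; `high_visits_low_content` gives timely initiation and 11–20
visits with probability 0.08 of any tracked intervention per visit —
the discordance pattern in which APNCU scores care adequate-or-better
on visit numbers while CTP flags the missing content.

## Comparison arithmetic

`cross_tabulate()` builds the 4×4 APNCU-by-CTP table (all sixteen
cells, zero-filled); `marginal_proportions()` reports per-category
percentages rounded half-up to one decimal (the reporting convention
behind printed values such as 45.3%; base R's round-half-to-even would
disagree at some boundaries); `agreement_summary()` splits each APNCU
row at the CTP Sufficient boundary, retaining raw counts; and
`chi_square()` runs Pearson's test of independence without continuity
correction, pruning all-zero rows/columns and flagging expected cells
below 5 (sparse category tables routinely trigger this, and the
development table does). `development_crosstab()` reconstructs that
published table through `cross_tabulate()` for use as a worked example.

## Numerical and design choices

* Counts and weeks are integers end to end; the only real-valued
  quantity is the observed/expected ratio, compared against exact
  decimal thresholds (0.50, 0.80, 1.10) — at most one division, so no
  tolerance machinery is needed.
* Ties in visit weeks are legal everywhere; CTP never counts visits and
  APNCU never reads weeks beyond the first, so granularity cannot leak
  into labels (tested as an invariant).
* Batch classification is order-independent and, by default, lenient:
  per-woman failures are collected into an `errors` attribute rather
  than aborting the cohort; `strict = TRUE` inverts this.
* All CLI randomness flows from a single `--seed`; simulation is
  reproducible bit-for-bit for a given seed on a given R version.
* Problem sizes used by the shipped checks — 2,000 women for
  calibration medians, 500 for the discordance scenario, ~26,000
  grid cases for the rule-table equivalence checks — were chosen as
  comfortable Monte-Carlo sizes for the quantities measured.

## Limitations

The CTP tool here is the three-indicator basic package: no risk
adjustment, no additional content indicators (weight, urine, fundal
height, counselling), and no over-use penalty when minima are met —
each a deliberate boundary of the instrument, not an oversight of the
implementation. The GINDEX index is out of scope. Chi-square p-values
on sparse 4×4 tables are asymptotic and flagged accordingly.
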