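# carescore

Rule-based adequacy scoring of antenatal (prenatal) care trajectories
from visit-level records, for health-services researchers and
epidemiologists.

Two instruments are implemented over a common data model:

* **CTP** (Content and Timing of care in Pregnancy) — a four-category
  ordinal tool, *Inadequate < Intermediate < Sufficient < Appropriate*,
  driven by (i) initiation of care by 14 completed weeks, (ii)
  whole-pregnancy counts of three basic interventions — ultrasound
  (US), blood pressure (BP), blood screening (BS) — against lower
  ranges (US ≥ 2, BP ≥ 6, BS ≥ 2) and configurable upper ranges, and
  (iii) per-trimester timing minima (T1 ≥ 1 US + 1 BP + 1 BS, T2 ≥
  1 US + 2 BP, T3 ≥ 3 BP + 1 BS).
* **APNCU** (Adequacy of Prenatal Care Utilization, Kotelchuck) —
  *Inadequate < Intermediate < Adequate < AdequatePlus*, from the
  initiation month and the ratio R of observed to expected visits under
  a recommended-visit schedule (ACOG or Belgian): late initiation or
  R < 0.50 → Inadequate; 0.50 ≤ R < 0.80 → Intermediate; 0.80 ≤ R <
  1.10 → Adequate; R ≥ 1.10 → AdequatePlus.

The package also ships a calibrated synthetic-cohort simulator (no
visit-level antenatal dataset of this kind is publicly deposited), the
4×4 cross-tabulation / agreement / chi-square machinery for comparing
the two classifications, and a command-line interface. See the methods
vignette (`vignettes/carescore-methods.Rmd`) for the full model
description and design choices.

## Worked example

```r
library(carescore)

# A woman with 8 ultrasounds but only one BP and one BS: many contacts,
# little recommended content.
t <- care_trajectory("w1", weeks = seq(6, 34, by = 4), us = 1,
                     bp = c(1, rep(0, 7)), bs = c(1, rep(0, 7)),
                     ga_at_delivery = 40)
classify_ctp(t)
#> CTP: Intermediate (woman w1)
#>   initiation at week 6 (cutoff 14): timely
#>   counts US=8 BP=1 BS=1 vs lower 2/6/2, upper 7/10/10
#>   below lower range (BP,BS) but above upper range (US) -> Intermediate
classify_apncu(t, apncu_schedule("belgian"))
#> APNCU: Adequate (woman w1, 8/10 visits)
#>   initiation at week 6 (timely through week 17): timely
#>   observed 8 / expected 10 visits = ratio 0.800 [schedule belgian]
#>   ratio band -> Adequate
```

The same care is "Adequate" on visit counting and only "Intermediate"
once content is examined — the discordance the CTP tool was built to
expose. On the development cohort's published 4×4 table this
arithmetic looks like:

```r
tab <- development_crosstab()          # N = 333
marginal_proportions(tab, "columns")   # CTP:   10.2  8.4 36.0 45.3 (%)
marginal_proportions(tab, "rows")      # APNCU:  2.4  6.9 32.1 58.6 (%)
agreement_summary(tab)[3:4, c("apncu", "n_ctp_high", "pct_ctp_high")]
#>          apncu n_ctp_high pct_ctp_high
#> 3     Adequate         86         80.4
#> 4 AdequatePlus        176         90.3
chi_square(tab)
#> Pearson chi-square: X2 = 122.858, df = 9, p = 3.47e-22 (expected cell < 5: ...)
```

80.4% of APNCU-Adequate and 90.3% of APNCU-AdequatePlus women score
Sufficient or Appropriate on CTP; the remaining 21/107 and 19/195 are
the women whose visit numbers looked adequate but whose care lacked the
recommended content or timing.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "carescore", package = "carescore"))')
Rscript "$CLI" simulate --preset study_like --n 333 --seed 42 --out cohort.csv
Rscript "$CLI" classify --input cohort.csv --out labels.csv
Rscript "$CLI" compare  --cohort cohort.csv --schedule belgian --out report.json
Rscript "$CLI" dump-config ctp
```

Exit codes: 0 success, 2 usage, 3 I/O, 4 validation.

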