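# surgicost

Micro-costing of surgical hospitalizations from hospital cost-center
ledgers and activity data.

## The problem

What does one surgical hospitalization — admission, ward stay, surgery,
ICU, discharge — actually cost the hospital? Tariff tables and
reimbursement values answer a different question; hospital managers and
health-economics analysts need the cost built from the institution's own
expenses. Pricing every item per patient (bottom-up) is accurate but so
laborious that published studies rarely cover more than a handful of
procedures. `surgicost` implements the pragmatic middle ground used in
hospital cost accounting: **micro-costing with top-down valuation**.
Supplies and medicines consumed during surgery are costed directly from
each surgery's consumption note; everything else is absorbed into cost
centers and apportioned by activity drivers, so that *every* procedure a
hospital performs can be costed from two routine exports — an
absorption-costing ledger and the hospital information system's encounter
table.

## The model

Five cost centers carry the indirect cost: the operating rooms of the
surgical center, the surgical ward (UICC), the intensive care unit (ICU),
the exam services (laboratory + imaging) and the admission office (NIR).
For an accounting period with ledger totals `C_center` (split into
non-personnel and personnel parts) and activity denominators from the
census, the unit rates are

    r_UICC = C_UICC / patient-days_UICC        (per ward day)
    r_ICU  = C_ICU  / patient-days_ICU         (per ICU day)
    r_exam = C_EXAMS / exams_total             (per exam, hospital-wide)
    r_NIR  = C_NIR  / admissions_total         (per admission)
    r_OR,room = C_OR,room / surgeries_room     (per surgery)

For a procedure with `n` surgeries the cost has three blocks:

* **Operating room** = median(consumption-note direct costs) +
  Σ_room (n_room / n) · r_OR,room
* **Hospitalization** = r_UICC · mean LOS_UICC + r_ICU · mean LOS_ICU +
  r_exam · mean exam count + r_NIR (personnel excluded)
* **Personnel** = the same five drivers applied to the personnel rates,
  kept segregated so hospitals with different hiring models stay
  comparable

and **total = Operating room + Hospitalization + Personnel**, covering
the full admission-to-discharge window. The median shields the direct
cost from occasional very expensive cases; lengths of stay enter as
arithmetic means. Because each rate is `total / denominator`, rate ×
denominator reconstructs every ledger total exactly — a conservation
property the test suite asserts throughout.

## Worked example

A micro-hospital with two operating rooms, round ledger totals and one
procedure (X, three surgeries in room R1):

```r
library(surgicost)
library(tibble)

ledger <- tibble(
  period = "2022-01",
  cost_center = rep(c("OPERATING_ROOM", "UICC", "ICU", "EXAMS", "NIR"), each = 2),
  room_id = NA_character_,
  resource = rep(c("Electricity", "Personnel"), 5),
  amount = c(800, 400, 1000, 600, 900, 300, 500, 250, 200, 100)
)
census <- hospital_census("2022-01",
  total_admissions = 20, surgical_admissions = 8,
  total_exams = 100, surgical_exams = 40,
  uicc_patient_days = 100, icu_patient_days = 30,
  surgeries_by_room = c(R1 = 5, R2 = 3))

schedule <- compute_unit_costs(ledger, census)
schedule
#> <unit_cost_schedule> period 2022-01
#>   rates (non-personnel / personnel):
#>     UICC daily:      10 / 6
#>     ICU daily:       30 / 10
#>     per exam:        5 / 2.5
#>     per admission:   10 / 5
#>     per surgery R1:  100 / 50
#>     per surgery R2:  100 / 50
```

The 1000 spent on the ward over 100 patient-days gives 10 per day; the 800
of pooled operating-room overhead over 8 surgeries gives 100 per surgery,
and so on. Costing procedure X (consumption notes 120/150/200, mean stays
5 ward and 1 ICU days, mean 5 exams):

```r
encounters <- tibble(
  encounter_id = c("e1", "e2", "e3"), period = "2022-01", type = "surgical",
  procedure_code = "X", room_id = "R1",
  direct_supplies_cost = c(120, 150, 200),
  los_uicc_days = c(4, 6, 5), los_icu_days = c(0, 2, 1),
  exam_count = c(4L, 6L, 5L))

cost_all_procedures(ledger, encounters, census)
#>   procedure_code operating_room_cost hospitalization_cost personnel_cost total
#> 1              X                 250                  115          107.5 472.5
```

Reading the 472.5: the operating room block is the median consumption
note (150) plus the per-surgery overhead (100); hospitalization is
10×5 + 30×1 + 5×5 + 10 = 115; personnel is 50 + 6×5 + 10×1 + 2.5×5 + 5 =
107.5.

## Command line

```sh
surgicost compute --ledger ledger.csv --encounters encounters.csv \
    [--census census.csv] [--config config.yaml] --out costs.csv
surgicost rates    ... --out rates.csv
surgicost simulate [--params params.yaml] --seed 7 --out fixture_dir/
```

`compute` writes one row per procedure with the full sub-component
breakdown, rounded half-even; `rates` emits the unit-cost schedule;
`simulate` writes a synthetic hospital (ledger, encounters, census and
ground-truth rates) for testing pipelines. CSV schemas are documented in
`?surgicost_schemas`; a `--dialect br`-style config switch handles
semicolon/comma exports.

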