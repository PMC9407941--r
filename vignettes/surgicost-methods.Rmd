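---
title: "Costing surgical hospitalizations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing surgical hospitalizations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgicost)
library(tibble)
```

## The costing problem

A surgical hospitalization runs from the administrative admission at the
hospital's regulation office (NIR), through the surgical ward (UICC), the
operating room, possibly the ICU, and back to discharge. From the
hospital's perspective its cost is everything spent on the patient over
that window. `surgicost` computes it with micro-costing under top-down
valuation: resource use is identified at component level, but monetary
value is assigned by dividing aggregate cost-center expenditures by
activity denominators rather than pricing each patient's items. The one
exception is the consumption note — the itemized supplies and medicines
spent during surgery — which hospital information systems record per
surgery and which is therefore costed directly.

Two routine exports drive the computation:

* an absorption-costing ledger: one monetary amount per (period, cost
  center, resource category), for five centers (operating rooms, UICC,
  ICU, exams, NIR) and fifteen resource categories of which `Personnel`
  is one;
* an encounter table covering *all* hospitalizations of the period, not
  only surgical ones: non-surgical admissions carry no procedure or
  consumption note, but they consume exams and admissions and therefore
  belong in the denominators.

## Unit rates and the three blocks

`compute_unit_costs()` derives, separately for non-personnel and
personnel ledger entries,

| rate | numerator | denominator |
|---|---|---|
| UICC daily | UICC center total | UICC patient-days (all patients) |
| ICU daily | ICU center total | ICU patient-days |
| per exam | exam-center total | hospital-wide exam count |
| per admission | NIR center total | total admissions |
| per surgery (per room) | operating-room total | surgeries in the room |

`cost_surgical_hospitalization()` then assembles, per procedure, the
Operating-room block (median direct cost + room-weighted per-surgery
rate), the Hospitalization block (daily rates × mean LOS, exam cost, NIR
cost; personnel excluded) and the segregated Personnel block (the same
drivers applied to the personnel rates). The segregation keeps results
comparable across institutions with different hiring models; a
configuration option lets additional resource categories (e.g.
outsourced staff) count as personnel.

Because every rate is a quotient of a ledger total by its realized
denominator, multiplying back reconstructs the totals: no cost is created
or lost by the apportionment. `check_conservation()` exposes this
property, and the test suite asserts it on every synthetic instance.

## Decisions where the accounting convention is open

Several points admit more than one defensible reading; the package fixes
them as follows.

**Median with even counts.** The direct cost is the median consumption
note; for an even number of surgeries the mean of the two middle values
is used (the standard convention, `stats::median`).

**"Average" length of stay is the arithmetic mean.** The median is
reserved for the consumption notes, where single very expensive cases
are common; stay lengths enter as means, which also makes the
per-procedure mean of bottom-up encounter costs coincide with the
top-down block formulas (the linearity that the oracle tests exploit).

**Exam allocation.** The default (`exam_mode = "per_exam"`) charges each
procedure its mean exam count times the hospital-wide per-exam rate.
Summed over all surgical encounters this equals the surgical proportion
of the exam-center total — the aggregate proration stated by the model —
while letting exam-heavy procedures cost more than exam-light ones.
`exam_mode = "flat_share"` is the literal aggregate reading: the
surgical share of the exam total divided evenly over surgical
admissions, identical for every procedure. Both are implemented; the
default was chosen for procedure-level resolution, since the exam count
is named a main cost driver.

**Admission-office allocation.** Prorating the NIR total by the surgical
share of admissions and then dividing over surgical admissions is
algebraically `NIR total / total admissions` per hospitalization, so the
per-admission rate is applied directly.

**Operating-room granularity.** `or_mode = "pooled"` (default) matches a
ledger that books the surgical center as one cost center: the total is
split by the proportion of surgeries in each room, which collapses to a
uniform per-surgery rate. `or_mode = "per_room"` expects one ledger
sub-center per room and gives genuinely room-specific rates. The default
reflects the more common single-center ledger layout.

**One period per run.** All inputs must carry the same period
identifier; multi-period data are processed period by period with no
cross-period averaging.

**Stay lengths are taken as recorded.** Fractional days are accepted and
never re-derived from timestamps; a same-day stay may legitimately be
recorded as 0 by the data producer.

**Zero denominators.** A center with positive cost but zero driver total
is a hard error — the cost would be stranded with no activity to absorb
it — while zero cost with zero driver yields a zero rate.

## Numeric conventions

Currency arithmetic uses double-precision floating point throughout;
nothing is rounded internally. The conservation, bottom-up-equivalence
and recovery properties are asserted at relative tolerances of 1e-9
(1e-12 for rate recovery), far below any monetary resolution; in
practice the observed errors sit at machine precision (~1e-16). Rounding
happens once, at report-writing time, half-even (banker's rounding, the
IEEE default that `round()` implements) to `rounding_decimals` (default
2), and reports are written with fixed decimals (`472.50`) so a re-read
reproduces the rounded values bit-exactly. Output rows are sorted by
procedure code and room maps by room id, making repeated runs
byte-identical.

Degenerate inputs are handled explicitly: an empty ledger yields all-zero
rates (a procedure then costs exactly its median consumption note); a
procedure that never enters the ICU pays no ICU per-diem; an encounter
table without surgical rows produces an empty report with a warning
rather than an error.

## The synthetic hospital

No public dataset pairs an absorption-costing ledger with an encounter
export, so verification rests on `simulate_hospital()`: it draws
encounters per procedure, aggregates their realized denominators into a
census, and *constructs* the ledger from known ground-truth unit rates
(`total = rate × realized denominator` in exact mode). That inversion
makes three strong oracles available on every simulated instance:
conservation must hold, `compute_unit_costs()` must return exactly the
ground-truth rates, and the engine's per-procedure breakdowns must equal
an independent bottom-up accumulation (price each encounter at the
rates, then take median direct + mean indirect per procedure).

Default distributions are plausible round figures for a mid-size public
general hospital in local currency units, chosen once and not fitted to
any real institution: ward stays as rounded lognormals around 3 days,
ICU use in 5–95% of surgeries by procedure with short lognormal stays,
exam counts Poisson with per-procedure rates between 2 and 12,
consumption notes lognormal between roughly 800 and 5000, three
operating rooms with unequal load, 10 procedures of 3–20 surgeries plus
150 non-surgical admissions, and unit rates such as 150/day ward
overhead versus 250/day ward personnel. A `perturbed` mode multiplies
each ledger amount by lognormal noise, emulating costs the drivers do
not explain; conservation still holds on the recomputed rates, while
recovery of the original truth intentionally fails.

What the generator does *not* emulate bounds what green tests show about
real data: driver values are independent across encounters (no
LOS–severity–cost correlation), there is no seasonality or case-mix
drift, ledgers are complete and consistent by construction, and the
exact mode assumes the rates fully explain the centers' costs. Passing
tests therefore demonstrate that the accounting arithmetic is correct
and self-consistent, not that any particular hospital's exports are
clean — which is why the readers validate row by row and refuse files
with errors.

## Problem sizes in the test and acceptance runs

The property suites run on simulated hospitals of about 60–120 surgical
encounters across 6–10 procedures plus 40–150 other admissions: 100
seeds for conservation and proration equivalence, 100 for bottom-up
equivalence, 50 for rate recovery. These sizes give every center and
room non-trivial activity while keeping the full suite under half a
minute; the properties are scale-free (they hold by algebra, not by
asymptotics), so larger instances add runtime, not information.

## Limitations

The package models costing, not economics: no cost-effectiveness
analysis, no comparison against reimbursement tables, no inflation or
currency conversion, no discounting. It consumes generic CSV exports
rather than connecting to live hospital systems, and it offers no
bottom-up costing variant beyond the internal verification oracle. The
model presumes the hospital operates both a cost system (absorbed cost
centers) and an information system recording per-surgery consumption
notes, stays and exam counts — where those are missing, there is nothing
to apportion.
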