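Package: surgicost
Title: Micro-Costing of Surgical Hospitalizations from Cost-Center Ledgers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated micro-costing top-down model for the cost of a
    surgical hospitalization, from admission to discharge. Derives unit
    rates (per patient-day, per exam, per admission, per surgery) by
    apportioning cost-center ledger totals over hospital-wide activity
    denominators, then assembles per-procedure costs in three blocks:
    Operating room (median consumption-note direct cost plus prorated
    indirect cost), Hospitalization (ward, ICU, exams, admission office)
    and Personnel (segregated, same drivers). Includes validated CSV
    readers/writers for ledger, encounter and census exports, a command
    line interface, and a synthetic-hospital generator with known
    ground-truth rates for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
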