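#' Canonical resource categories
#'
#' The fifteen resource categories that an absorption-costing ledger
#' allocates to hospital cost centers. "Personnel" is the only category
#' flagged as personnel by default; [cost_config()] can extend that flag
#' (e.g. to outsourced staff recorded under another heading) to support
#' institutions with different hiring models.
#'
#' @return Character vector of the fifteen canonical category names.
#' @export
#' @examples
#' resource_categories()
resource_categories <- function() {
  c(
    "Personnel",
    "Hospital Medical Supplies and Medicines used in the infirmary",
    "Patient Removal",
    "Nutrition and Dietetics Service",
    "Clothing",
    "Common Waste Collection",
    "Cleanliness and conservation",
    "Maintenance and Conservation of Real Estate",
    "Maintenance and Conservation of Machines and Equipment",
    "Reception",
    "Surveillance and/or Security",
    "Water and sewage",
    "Data communication",
    "Electricity",
    "Telecommunications"
  )
}

#' Cost-center kinds
#'
#' The five cost centers of the model: the operating rooms of the surgical
#' center (`OPERATING_ROOM`, the only kind that may carry a `room_id`), the
#' surgical ward (`UICC`), the intensive care unit (`ICU`), laboratory and
#' imaging exams (`EXAMS`) and the administrative admission office (`NIR`).
#'
#' @return Character vector of the five cost-center identifiers.
#' @export
cost_centers <- function() {
  c("OPERATING_ROOM", "UICC", "ICU", "EXAMS", "NIR")
}
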