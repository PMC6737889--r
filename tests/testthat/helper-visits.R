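# The worked three-visit example used across tests: a patient whose HbA1c
# moves 8.1 -> 9.1 -> 8.0 under ~20-unit doses.
worked_visits <- function() {
  tibble::tibble(
    patient_id = 1L,
    visit = 1:3,
    hba1c = c(8.1, 9.1, 8),
    body_mass_index = c(21.4, 24, 22),
    activity_level = 1,
    alcohol_usage = 1,
    lantus_dose = c(20, 22, 21)
  )
}
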