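# Fixtures are built in code: hand-made hospital profiles and patient
# tables so tests can control volumes and degradation mechanisms exactly.

mk_hospitals <- function(volumes, cr = 1, dr = 1, mr = 1, tm = 0,
                         type = "teaching") {
  n <- length(volumes)
  tibble::tibble(
    facility_id = sprintf("H%03d", seq_len(n)),
    hospital_type = rep(type, length.out = n),
    volume = volumes,
    case_report_prob = rep(cr, length.out = n),
    death_report_prob = rep(dr, length.out = n),
    comorbidity_report_prob = rep(mr, length.out = n),
    tnm_missing_prob = rep(tm, length.out = n)
  )
}

# A raw registry table of n identical reference-level patients: male, age
# at the default center, ASA 0, scores 0, BMI below 24, lobectomy via
# thoracotomy, stage I / N0 / R0, no comorbidities.  Individual columns
# are then overwritten by tests as needed.
ref_patients <- function(n, facility_id = "H001") {
  df <- tibble::tibble(
    facility_id = rep(facility_id, n),
    sex = "male", age = 64, asa = 0L, performance_status = 0L,
    dyspnea = 0L, fev = 83, bmi = 20, procedure = "lobectomy",
    approach = "thoracotomy", ptumor = "I", pnodes = "0",
    resection = "R0", death = 0L
  )
  for (v in comorbidity_fields()) df[[v]] <- 0L
  df
}

# Simulated single-facility registry drawn from the default case mix and
# true model (patient count is Poisson around n).
sim_patients <- function(n, seed, model = true_model(),
                         casemix = casemix_config(), facility_id = "H001") {
  h <- mk_hospitals(n)
  h$facility_id <- facility_id
  generate_admin_registry(h, casemix, model, seed = seed)
}
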