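#' Generate hospital profiles with data-reporting mechanisms
#'
#' Each hospital carries an expected two-year case volume, a type, and
#' four reporting mechanisms that govern how its clinical-registry entry
#' degrades relative to the complete administrative record:
#' `case_report_prob` (a patient appears in the clinical registry at
#' all), `death_report_prob` (a recorded patient's death is recorded as
#' a death), `comorbidity_report_prob` (a true comorbidity flag is
#' coded), and `tnm_missing_prob` (staging/resection fields are blanked
#' on top of their baseline missingness).
#'
#' Scenarios:
#' \describe{
#'   \item{`"clean"`}{all report probabilities 1, no extra staging
#'     blanking — the clinical registry equals the administrative truth.}
#'   \item{`"paper-like"`}{about 25\% of hospitals report well (all
#'     report probabilities in \[0.93, 1\], extra staging blanking below
#'     12\%); the rest have at least one degraded mechanism — most
#'     under-report cases (case reporting U(0.25, 0.68), matching an
#'     observed median clinical/administrative case ratio near 0.46,
#'     with death recording U(0.5, 0.95) so the joint death ratio
#'     centers near 0.33), the others record cases nearly completely
#'     but miss deaths (death recording U(0.35, 0.7)); degraded
#'     hospitals also under-code
#'     comorbidities (U(0.5, 0.95)) and blank staging more often
#'     (U(0.10, 0.40)).}
#' }
#'
#' Volumes are log-normal (median 130 cases over two years, log-sd 1,
#' floor 10), mimicking the observed skew of per-hospital caseloads.
#' Draws are split per hospital from the master seed, so extending the
#' list leaves earlier hospitals unchanged.
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param seed Integer master seed.
#' @param degradation_scenario `"clean"` or `"paper-like"`.
#' @return Tibble with one row per hospital (class includes
#'   `hospital_profiles`).
#' @export
generate_hospitals <- function(n_hospitals, seed,
                               degradation_scenario = c("clean", "paper-like")) {
  stopifnot(n_hospitals >= 2)
  degradation_scenario <- match.arg(degradation_scenario)

  rows <- lapply(seq_len(n_hospitals), function(i) {
    with_seed(hospital_seed(seed, i, purpose = 1L), {
      volume <- max(10, round(rlnorm(1, meanlog = log(130), sdlog = 1)))
      type <- sample(c("teaching", "non-teaching", "private"), 1,
                     prob = c(0.33, 0.21, 0.46))
      if (degradation_scenario == "clean") {
        cr <- 1; dr <- 1; mr <- 1; tm <- 0
      } else {
        if (runif(1) < 0.25) {           # well-reporting hospital
          cr <- runif(1, 0.93, 1)
          dr <- runif(1, 0.93, 1)
          mr <- runif(1, 0.90, 1)
          tm <- runif(1, 0.02, 0.12)
        } else {                          # at least one degraded mechanism
          if (runif(1) < 0.7) {           # case under-reporting
            cr <- runif(1, 0.25, 0.68)
            dr <- runif(1, 0.5, 0.95)
          } else {                        # death under-recording
            cr <- runif(1, 0.85, 1)
            dr <- runif(1, 0.35, 0.7)
          }
          mr <- runif(1, 0.5, 0.95)
          tm <- runif(1, 0.10, 0.40)
        }
      }
      tibble::tibble(
        facility_id = sprintf("F%05d", i),
        hospital_type = type,
        volume = volume,
        case_report_prob = cr,
        death_report_prob = dr,
        comorbidity_report_prob = mr,
        tnm_missing_prob = tm
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hospital_profiles", class(out))
  attr(out, "scenario") <- degradation_scenario
  attr(out, "seed") <- seed
  out
}
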