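#' Write a simulated cohort to delimited analysis files
#'
#' Writes `patients.csv`, `labs.csv` and `regimens.csv` (comma-separated,
#' ISO-8601 dates, UTF-8, header row) and, when `with_oracle = TRUE`,
#' `oracle.csv` carrying the latent truth. The analysis files contain no
#' latent or oracle columns: `baseline_egfr` and `initial_regimen` are
#' dropped from `patients.csv` because the preparation stage re-derives them
#' from the laboratory and regimen files.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param with_oracle also write `oracle.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, with_oracle = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  patients <- cohort$patients %>%
    select(-dplyr::any_of(c("baseline_egfr", "initial_regimen")))
  readr::write_csv(patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$labs, file.path(dir, "labs.csv"))
  readr::write_csv(cohort$regimens, file.path(dir, "regimens.csv"))
  if (isTRUE(with_oracle)) {
    readr::write_csv(cohort$latent, file.path(dir, "oracle.csv"))
  }
  invisible(dir)
}

#' Read cohort analysis files
#'
#' @param dir directory holding `patients.csv`, `labs.csv`, `regimens.csv`.
#' @return List with `patients`, `labs`, `regimens` tibbles.
#' @export
read_cohort <- function(dir) {
  spec_p <- readr::cols(
    patient_id = readr::col_character(),
    art_start_date = readr::col_date(),
    sex = readr::col_character(),
    hiv_exposure = readr::col_character(),
    .default = readr::col_guess()
  )
  list(
    patients = readr::read_csv(file.path(dir, "patients.csv"),
                               col_types = spec_p, progress = FALSE),
    labs = readr::read_csv(file.path(dir, "labs.csv"),
                           col_types = readr::cols(
                             patient_id = readr::col_character(),
                             date = readr::col_date(),
                             .default = readr::col_double()
                           ), progress = FALSE),
    regimens = readr::read_csv(file.path(dir, "regimens.csv"),
                               col_types = readr::cols(
                                 patient_id = readr::col_character(),
                                 start_date = readr::col_date(),
                                 stop_date = readr::col_date(),
                                 components = readr::col_character()
                               ), progress = FALSE)
  )
}
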