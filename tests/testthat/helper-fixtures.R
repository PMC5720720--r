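# Small in-code fixtures shared across test files.

# one-row-per-patient baseline table with sensible defaults
make_patients <- function(n = 1, start = as.Date("2006-01-01"), ...) {
  out <- tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    art_start_date = rep(as.Date(start), length.out = n),
    age_at_start = 40,
    sex = "male",
    hiv_exposure = "heterosexual",
    nadir_cd4 = 250,
    baseline_cd4 = 300,
    baseline_vl_log10 = 4.5,
    hbv = FALSE, hcv = FALSE, diabetes = FALSE, hypertension = FALSE,
    cvd = FALSE
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# labs for one patient from (day, egfr) pairs; creatinine back-computed with
# the same MDRD inversion the package uses, so eGFR round-trips
make_labs <- function(patients, days, egfr, cd4 = 300, vl = 50) {
  stopifnot(nrow(patients) == 1)
  tibble::tibble(
    patient_id = patients$patient_id,
    date = patients$art_start_date + days,
    scr = scr_from_egfr(egfr, patients$age_at_start + days / 365.25,
                        patients$sex),
    cd4 = cd4, vl = vl
  )
}

make_regimens <- function(patients, components = "TDF+FTC+EFV",
                          start_days = 0, stop_days = 730) {
  tibble::tibble(
    patient_id = rep(patients$patient_id[1], length(components)),
    start_date = patients$art_start_date[1] + start_days,
    stop_date = patients$art_start_date[1] + stop_days,
    components = components
  )
}

# hand-rolled person-month rows for model-fitting tests: one patient per
# element of `time` with a single terminal month at `time` (monthly rows
# from 1..time), exposure via initial_regimen
make_pm_cohort <- function(time, event, regimen) {
  stopifnot(length(time) == length(event), length(time) == length(regimen))
  purrr::map_dfr(seq_along(time), function(i) {
    m <- seq_len(time[i])
    tibble::tibble(
      patient_id = sprintf("S%03d", i),
      month = m,
      tstart = m - 1,
      tstop = as.numeric(m),
      current_regimen = regimen_factor(regimen[i]),
      previous_regimen = regimen_factor(NA),
      on_initial = TRUE,
      cd4_cat = cd4_category(150 + 40 * (i %% 8)),
      vl_cat = vl_category(10^(1 + (i %% 4))),
      egfr_cat = egfr_category(65 + 10 * (i %% 5)),
      event = event[i] & m == time[i],
      switched_this_month = FALSE,
      censored_this_month = !event[i] & m == time[i],
      age_at_start = 30 + (i %% 25), sex = c("male", "female")[1 + i %% 2],
      hiv_exposure = c("homosexual", "heterosexual", "other")[1 + i %% 3],
      nadir_cd4 = 150 + 20 * (i %% 10), baseline_cd4 = 200 + 25 * (i %% 10),
      baseline_vl_log10 = 3.5 + 0.3 * (i %% 6),
      baseline_egfr = 70 + 8 * (i %% 9), year_of_start = 2004L + (i %% 9),
      hbv = i %% 11 == 0, hcv = i %% 7 == 0, diabetes = i %% 13 == 0,
      hypertension = i %% 5 == 0, cvd = i %% 17 == 0,
      initial_regimen = regimen_factor(regimen[i])
    )
  })
}

# brute-force Cox partial likelihood for a single binary covariate on
# right-censored monthly data (no left truncation, Efron irrelevant when all
# event times are distinct)
cox_loglik_1cov <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# five-patient eligibility fixture: one violation per rule plus a compliant
# patient; shared by the unit and acceptance suites
eligibility_fixture <- function() {
  pts <- dplyr::bind_rows(
    make_patients(start = "2006-03-01", patient_id = "OK"),
    make_patients(start = "2003-06-01", patient_id = "EARLY"),
    make_patients(start = "2006-03-01", patient_id = "NOBASE"),
    make_patients(start = "2006-03-01", patient_id = "LOWEGFR"),
    make_patients(start = "2006-03-01", patient_id = "ONEPOST")
  )
  # labs carry day/egfr directly so boundary values (exactly 60) are exact
  lab_for <- function(id, days, egfr) {
    tibble::tibble(patient_id = id, day = days, egfr = egfr)
  }
  labs <- dplyr::bind_rows(
    lab_for("OK", c(-30, 90, 180), c(100, 95, 92)),
    lab_for("EARLY", c(-30, 90, 180), c(100, 95, 92)),
    lab_for("NOBASE", c(-200, 90, 180), c(100, 95, 92)),
    lab_for("LOWEGFR", c(-30, 90, 180), c(60, 95, 92)),
    lab_for("ONEPOST", c(-30, 90), c(100, 95))
  )
  list(patients = pts, labs = labs)
}

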