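#' Baseline eGFR from the pre-treatment creatinine window
#'
#' Baseline eGFR is the value from the latest serum creatinine in the closed
#' 180-day window before ART initiation (day -180 included, day 0 included).
#'
#' @param labs tibble of one patient's laboratory rows with columns `day`
#'   (days relative to ART start, negative before) and `egfr`.
#' @param window_days width of the pre-treatment window (default 180).
#' @return The baseline eGFR, or `NA_real_` if no creatinine falls in the
#'   window.
#' @export
select_baseline_egfr <- function(labs, window_days = 180) {
  ok <- !is.na(labs$egfr) & labs$day >= -window_days & labs$day <= 0
  if (!any(ok)) return(NA_real_)
  labs$egfr[ok][which.max(labs$day[ok])]
}

#' Apply the cohort eligibility rules
#'
#' Patients are retained when (i) they started ART on or after
#' `min_start_date`, (ii) a baseline eGFR exists (creatinine within 180 days
#' before start) and exceeds 60 ml/min/1.73m2 strictly, and (iii) at least two
#' creatinine measurements follow ART initiation. The exclusion log records
#' the first failing rule per dropped patient, in that order.
#'
#' @param patients patient baseline tibble (`patient_id`, `art_start_date`,
#'   `age_at_start`, `sex`, ...).
#' @param labs laboratory tibble with `patient_id`, `date`, `scr` (mg/dL;
#'   `NA` for non-creatinine rows), optionally `cd4`, `vl`.
#' @param min_start_date earliest eligible ART start (default `"2004-01-01"`).
#' @return List with `patients` (retained rows, plus `baseline_egfr` and
#'   `year_of_start`) and `exclusions` (tibble `patient_id`, `reason`).
#' @export
apply_eligibility <- function(patients, labs, min_start_date = "2004-01-01") {
  min_start_date <- as.Date(min_start_date)
  # baseline eGFR and start year are derived here; drop stale copies
  patients <- patients %>%
    select(-dplyr::any_of(c("baseline_egfr", "year_of_start")))
  labs <- add_lab_days(labs, patients)

  creat <- labs %>% filter(!is.na(.data$egfr))
  cand <- creat %>%
    filter(.data$day >= -180, .data$day <= 0) %>%
    arrange(.data$patient_id, .data$day)
  last_in_window <- !duplicated(cand$patient_id, fromLast = TRUE)
  post_counts <- table(creat$patient_id[creat$day > 0])
  base_egfr <- tibble(
    patient_id = cand$patient_id[last_in_window],
    baseline_egfr = cand$egfr[last_in_window]
  ) %>%
    full_join(tibble(patient_id = names(post_counts),
                     n_post = as.integer(post_counts)),
              by = "patient_id")

  pts <- patients %>%
    left_join(base_egfr, by = "patient_id") %>%
    mutate(
      n_post = tidyr::replace_na(.data$n_post, 0L),
      year_of_start = as.integer(format(.data$art_start_date, "%Y")),
      reason = case_when(
        .data$art_start_date < min_start_date ~ "pre_2004_start",
        is.na(.data$baseline_egfr) ~ "no_baseline_creatinine",
        .data$baseline_egfr <= 60 ~ "baseline_egfr_le_60",
        .data$n_post < 2 ~ "fewer_than_2_post_start_creatinines",
        TRUE ~ NA_character_
      )
    )

  list(
    patients = pts %>% filter(is.na(.data$reason)) %>%
      select(-"reason", -"n_post"),
    exclusions = pts %>% filter(!is.na(.data$reason)) %>%
      select("patient_id", "reason")
  )
}

# attach day offsets and eGFR to a lab table (joins age/sex from patients);
# age at measurement date is used in the MDRD conversion
add_lab_days <- function(labs, patients) {
  if (all(c("day", "egfr") %in% names(labs))) return(labs)
  labs <- labs %>%
    inner_join(patients %>%
                 select("patient_id", "art_start_date", "age_at_start", "sex"),
               by = "patient_id") %>%
    mutate(day = as.numeric(as.Date(.data$date) - .data$art_start_date))
  labs$egfr <- rep(NA_real_, nrow(labs))
  has_scr <- !is.na(labs$scr)
  labs$egfr[has_scr] <- mdrd_egfr(
    labs$scr[has_scr],
    labs$age_at_start[has_scr] + labs$day[has_scr] / 365.25,
    labs$sex[has_scr]
  )
  labs %>% select(-"art_start_date", -"age_at_start", -"sex")
}

#' Detect a confirmed chronic kidney disease event
#'
#' A CKD event is the first eGFR below 60 ml/min/1.73m2 confirmed by a later
#' sub-60 measurement at least 90 days after it. Under the default strict
#' reading every measurement between the index and confirming values must also
#' be below 60; a single recovery at or above 60 voids the candidate and the
#' scan restarts after the interruption. `any_later_confirm = TRUE` relaxes
#' this so any later sub-60 value 90+ days out confirms.
#'
#' @param egfr_series tibble with columns `day` (days since ART start, sorted
#'   increasing) and `egfr`; only post-baseline rows (`day > 0`) are scanned.
#' @param gap_days minimum confirmation gap (default 90).
#' @param any_later_confirm relax the strictly-sustained requirement.
#' @return One-row tibble (`event_day`, `confirm_day`) or `NULL`.
#' @export
detect_ckd_event <- function(egfr_series, gap_days = 90,
                             any_later_confirm = FALSE) {
  s <- egfr_series %>%
    filter(!is.na(.data$egfr), .data$day > 0) %>%
    arrange(.data$day)
  hit <- detect_ckd_core(s$day, s$egfr, gap_days, any_later_confirm)
  if (is.null(hit)) return(NULL)
  tibble(event_day = hit[1], confirm_day = hit[2])
}

# the confirmation scan on bare vectors (day sorted increasing)
detect_ckd_core <- function(day, egfr, gap_days, any_later_confirm) {
  n <- length(day)
  i <- 1L
  while (i <= n) {
    if (egfr[i] < 60) {
      if (isTRUE(any_later_confirm)) {
        j <- which(egfr < 60 & day >= day[i] + gap_days & seq_len(n) > i)
        if (length(j) > 0) return(c(day[i], day[j[1]]))
        i <- i + 1L
      } else {
        j <- i + 1L
        while (j <= n && egfr[j] < 60) {
          if (day[j] >= day[i] + gap_days) return(c(day[i], day[j]))
          j <- j + 1L
        }
        # interrupted by a recovery (or ran out of data): restart after it
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  NULL
}

#' Detect confirmed CKD events for every patient
#'
#' @param labs laboratory tibble carrying `patient_id`, `day` and `egfr`
#'   columns (see [apply_eligibility()]), or raw labs plus `patients`.
#' @param patients optional patient table used to derive `day`/`egfr` when
#'   absent from `labs`.
#' @inheritParams detect_ckd_event
#' @return Tibble `patient_id`, `event_day`, `confirm_day` (zero rows if no
#'   events).
#' @export
detect_ckd_events <- function(labs, patients = NULL, gap_days = 90,
                              any_later_confirm = FALSE) {
  if (!all(c("day", "egfr") %in% names(labs))) {
    labs <- add_lab_days(labs, patients)
  }
  s <- labs %>%
    filter(!is.na(.data$egfr), .data$day > 0) %>%
    arrange(.data$patient_id, .data$day)
  idx <- split(seq_len(nrow(s)), s$patient_id)
  hits <- lapply(idx, function(ii) {
    detect_ckd_core(s$day[ii], s$egfr[ii], gap_days, any_later_confirm)
  })
  found <- !vapply(hits, is.null, logical(1))
  tibble(
    patient_id = names(hits)[found],
    event_day = unname(vapply(hits[found], `[`, numeric(1), 1)),
    confirm_day = unname(vapply(hits[found], `[`, numeric(1), 2))
  )
}

# last-value-carried-forward lookup on the month grid: for each query
# (patient, month) return the value of the latest observation available at
# that month's start. Vectorised via a combined sort key.
lvcf_lookup <- function(obs_pid, obs_month, obs_day, obs_val, q_pid, q_month) {
  keep <- !is.na(obs_val)
  obs_pid <- obs_pid[keep]; obs_month <- obs_month[keep]
  obs_day <- obs_day[keep]; obs_val <- obs_val[keep]
  if (length(obs_val) == 0) return(rep(NA_real_, length(q_pid)))
  big <- max(c(obs_month, q_month)) + 2
  o <- order(obs_pid, obs_month, obs_day)
  key_obs <- obs_pid[o] * big + obs_month[o]
  idx <- findInterval(q_pid * big + q_month, key_obs)
  out <- rep(NA_real_, length(q_pid))
  hit <- idx >= 1
  hit[hit] <- obs_pid[o][idx[hit]] == q_pid[hit]
  out[hit] <- obs_val[o][idx[hit]]
  out
}

#' Expand follow-up into person-month records
#'
#' Splits each eligible patient's follow-up into consecutive 30.44-day months
#' from ART start. Covariate categories (CD4, viral load, eGFR) are
#' last-value-carried-forward: the value governing month *m* is the most
#' recent measurement on or before that month's start day, with baseline
#' values seeding month 1. The regimen type active at the month start defines
#' `current_regimen`; `previous_regimen` is the type immediately before it.
#' The confirmed-CKD event is assigned to the month containing its index
#' (first sub-60) day and later months are dropped.
#'
#' @param patients eligible patient tibble (from [apply_eligibility()]),
#'   including `baseline_egfr` and `year_of_start`.
#' @param labs laboratory tibble (`patient_id`, `date`, `scr`, `cd4`, `vl`).
#' @param regimens regimen interval tibble (`patient_id`, `start_date`,
#'   `stop_date`, and `components` or `regimen`).
#' @param events tibble from [detect_ckd_events()].
#' @param month_days fixed month length in days (default 30.44).
#' @param admin_end_date database close date. Follow-up ending within one
#'   month of the patient's administrative horizon is treated as
#'   administrative censoring and is *not* flagged `censored_this_month`
#'   (only loss to follow-up is, since only that is modelled by the
#'   inverse-probability censoring weights). `NULL` flags every non-event,
#'   non-switch termination.
#' @return Person-month tibble: identifiers, month index and counting-process
#'   bounds (`tstart`, `tstop` in months), regimen columns, LVCF covariate
#'   categories, terminal flags, and the baseline covariates replicated per
#'   row.
#' @export
expand_person_months <- function(patients, labs, regimens, events,
                                 month_days = MONTH_DAYS,
                                 admin_end_date = "2013-12-31") {
  labs <- add_lab_days(labs, patients)
  regimens <- classify_regimen_table(regimens)

  pts <- patients %>% mutate(.pid = seq_len(nrow(patients)))
  rg <- regimens %>%
    inner_join(pts %>% select("patient_id", "art_start_date", ".pid"),
               by = "patient_id") %>%
    mutate(
      start_day = as.numeric(as.Date(.data$start_date) - .data$art_start_date),
      stop_day = ifelse(is.na(.data$stop_date), Inf,
                        as.numeric(as.Date(.data$stop_date) - .data$art_start_date))
    ) %>%
    arrange(.data$.pid, .data$start_day)
  # collapse runs of identical category: a within-type drug substitution is
  # not a switch
  nrg <- nrow(rg)
  new_pid <- c(TRUE, rg$.pid[-1] != rg$.pid[-nrg])
  chg <- new_pid | c(TRUE, rg$regimen[-1] != rg$regimen[-nrg])
  first_of_run <- which(chg)
  last_of_run <- c(first_of_run[-1] - 1L, nrg)
  reg <- tibble(
    .pid = rg$.pid[first_of_run],
    regimen = rg$regimen[first_of_run],
    start_day = rg$start_day[first_of_run],
    stop_day = rg$stop_day[last_of_run],
    previous_regimen = regimen_factor(
      ifelse(new_pid[first_of_run], NA,
             as.character(rg$regimen[c(1L, first_of_run[-1] - 1L)])))
  )

  # follow-up end: last covered day (finite regimen stop or last lab)
  fin_stop <- ifelse(is.finite(reg$stop_day), reg$stop_day, -Inf)
  end_reg_v <- tapply(fin_stop, reg$.pid, max)
  end_reg <- tibble(.pid = as.integer(names(end_reg_v)),
                    end_reg = as.numeric(end_reg_v))
  labs_pid <- labs %>%
    inner_join(pts %>% select("patient_id", ".pid"), by = "patient_id")
  end_lab_v <- tapply(labs_pid$day, labs_pid$.pid, max)
  end_lab <- tibble(.pid = as.integer(names(end_lab_v)),
                    end_lab = as.numeric(end_lab_v))
  ev <- events %>%
    inner_join(pts %>% select("patient_id", ".pid"), by = "patient_id")

  info <- pts %>%
    left_join(end_reg, by = ".pid") %>%
    left_join(end_lab, by = ".pid") %>%
    left_join(ev %>% select(".pid", "event_day"), by = ".pid") %>%
    mutate(
      end_day = pmax(.data$end_reg, .data$end_lab, 1, na.rm = TRUE),
      end_day = pmin(.data$end_day,
                     ifelse(is.na(.data$event_day), Inf, .data$event_day)),
      n_months = pmax(1L, as.integer(ceiling(.data$end_day / month_days - 1e-9))),
      event_month = ifelse(is.na(.data$event_day), NA_integer_,
                           pmax(1L, as.integer(ceiling(.data$event_day / month_days - 1e-9))))
    )

  pm <- tibble(
    .pid = rep(info$.pid, info$n_months),
    month = sequence(info$n_months)
  ) %>%
    mutate(month_start_day = (.data$month - 1) * month_days)

  # regimen interval active at each month start
  big_day <- max(c(reg$start_day, pm$month_start_day)) + 10
  o <- order(reg$.pid, reg$start_day)
  key_reg <- reg$.pid[o] * big_day + reg$start_day[o]
  idx <- findInterval(pm$.pid * big_day + pm$month_start_day + 1e-9, key_reg)
  valid <- idx >= 1
  valid[valid] <- reg$.pid[o][idx[valid]] == pm$.pid[valid] &
    reg$stop_day[o][idx[valid]] > pm$month_start_day[valid] - 1e-9
  if (any(!valid)) {
    warning(sum(!valid), " person-month(s) fell in a regimen coverage gap ",
            "and were excluded", call. = FALSE)
  }
  pm$current_regimen <- regimen_factor(NA)
  pm$current_regimen[valid] <- reg$regimen[o][idx[valid]]
  pm$previous_regimen <- regimen_factor(NA)
  pm$previous_regimen[valid] <- reg$previous_regimen[o][idx[valid]]

  # months in which a switch (category change) occurs: the month containing
  # the start day of each non-first collapsed interval
  sw <- reg %>%
    filter(!is.na(.data$previous_regimen), is.finite(.data$start_day)) %>%
    transmute(.pid = .data$.pid,
              sw_month = pmax(1L, as.integer(ceiling(.data$start_day / month_days - 1e-9)))) %>%
    distinct()
  pm <- pm %>%
    left_join(sw %>% mutate(switched_this_month = TRUE),
              by = c(".pid" = ".pid", "month" = "sw_month")) %>%
    mutate(switched_this_month = !is.na(.data$switched_this_month))

  # LVCF covariates: observed labs plus baseline seeds at day 0
  labs2 <- labs %>%
    inner_join(pts %>% select("patient_id", ".pid"), by = "patient_id") %>%
    mutate(avail_month = pmax(1L, as.integer(floor(.data$day / month_days - 1e-9) + 2)))
  seeds <- pts %>% transmute(
    .pid = .data$.pid, day = 0, avail_month = 1L,
    egfr = .data$baseline_egfr,
    cd4 = if ("baseline_cd4" %in% names(pts)) .data$baseline_cd4 else NA_real_,
    vl = if ("baseline_vl_log10" %in% names(pts)) 10^.data$baseline_vl_log10 else NA_real_
  )
  lv <- function(var) {
    ob <- bind_rows(
      labs2 %>% select(".pid", "avail_month", "day", value = dplyr::all_of(var)),
      seeds %>% select(".pid", "avail_month", "day", value = dplyr::all_of(var)) %>%
        mutate(day = -1e6)  # baseline seed loses ties against a measured value
    )
    lvcf_lookup(ob$.pid, ob$avail_month, ob$day, ob$value, pm$.pid, pm$month)
  }
  if (!"cd4" %in% names(labs2)) labs2$cd4 <- NA_real_
  if (!"vl" %in% names(labs2)) labs2$vl <- NA_real_
  pm$egfr_cat <- egfr_category(lv("egfr"))
  pm$cd4_cat <- cd4_category(lv("cd4"))
  pm$vl_cat <- vl_category(lv("vl"))

  # terminal flags; administrative end of follow-up is not "censoring" for
  # weighting purposes, only loss to follow-up is
  if (is.null(admin_end_date)) {
    info$ltfu <- TRUE
  } else {
    admin_day <- as.numeric(as.Date(admin_end_date) - info$art_start_date)
    info$ltfu <- info$end_day < admin_day - month_days - 1
  }
  pm <- pm %>%
    left_join(info %>% select(".pid", "n_months", "event_month", "ltfu"),
              by = ".pid") %>%
    mutate(
      event = !is.na(.data$event_month) & .data$month == .data$event_month,
      terminal = .data$month == .data$n_months,
      censored_this_month = .data$terminal & !.data$event &
        !.data$switched_this_month & .data$ltfu,
      switched_this_month = .data$switched_this_month & !.data$event
    )

  # on_initial: months up to and including the first switch month
  first_sw <- sw %>%
    arrange(.data$.pid, .data$sw_month) %>%
    distinct(.data$.pid, .keep_all = TRUE) %>%
    rename(first_sw = "sw_month")
  pm <- pm %>%
    left_join(first_sw, by = ".pid") %>%
    mutate(on_initial = is.na(.data$first_sw) | .data$month <= .data$first_sw)

  base_cols <- intersect(
    c("patient_id", "age_at_start", "sex", "hiv_exposure", "nadir_cd4",
      "baseline_cd4", "baseline_vl_log10", "baseline_egfr", "year_of_start",
      "hbv", "hcv", "diabetes", "hypertension", "cvd", "initial_regimen"),
    names(pts)
  )
  out <- pm %>%
    filter(valid) %>%
    left_join(pts %>% select(".pid", dplyr::all_of(base_cols)), by = ".pid") %>%
    transmute(
      patient_id = .data$patient_id,
      month = .data$month,
      tstart = .data$month - 1,
      tstop = as.numeric(.data$month),
      current_regimen = .data$current_regimen,
      previous_regimen = .data$previous_regimen,
      on_initial = .data$on_initial,
      cd4_cat = .data$cd4_cat,
      vl_cat = .data$vl_cat,
      egfr_cat = .data$egfr_cat,
      event = .data$event,
      switched_this_month = .data$switched_this_month,
      censored_this_month = .data$censored_this_month,
      !!!rlang::syms(setdiff(base_cols, "patient_id"))
    )
  out
}

#' Run the full data-preparation stage
#'
#' Convenience wrapper: eligibility screening, event detection, and
#' person-month expansion in one call.
#'
#' @inheritParams apply_eligibility
#' @inheritParams expand_person_months
#' @inheritParams detect_ckd_event
#' @return List with `person_months`, `patients` (eligible, with
#'   `baseline_egfr`, `year_of_start` and `initial_regimen`), `events`, and
#'   `exclusions`.
#' @export
prepare_cohort <- function(patients, labs, regimens,
                           min_start_date = "2004-01-01",
                           gap_days = 90, any_later_confirm = FALSE,
                           month_days = MONTH_DAYS,
                           admin_end_date = "2013-12-31") {
  elig <- apply_eligibility(patients, labs, min_start_date = min_start_date)
  pts <- elig$patients
  regimens <- classify_regimen_table(regimens)
  if (!"initial_regimen" %in% names(pts)) {
    init <- regimens %>%
      group_by(.data$patient_id) %>%
      arrange(.data$start_date, .by_group = TRUE) %>%
      summarise(initial_regimen = dplyr::first(.data$regimen), .groups = "drop")
    pts <- pts %>% left_join(init, by = "patient_id")
  }
  labs_d <- add_lab_days(labs, pts) %>%
    semi_join(pts, by = "patient_id")
  events <- detect_ckd_events(labs_d, gap_days = gap_days,
                              any_later_confirm = any_later_confirm)
  pm <- expand_person_months(pts, labs_d,
                             regimens %>% semi_join(pts, by = "patient_id"),
                             events, month_days = month_days,
                             admin_end_date = admin_end_date)
  list(person_months = pm, patients = pts, events = events,
       exclusions = elig$exclusions)
}
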