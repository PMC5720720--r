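test_that("baseline eGFR uses the last creatinine in the 180-day window", {
  labs <- tibble::tibble(day = c(-200, -30), egfr = c(80, 95))
  expect_equal(select_baseline_egfr(labs), 95)
  expect_true(is.na(select_baseline_egfr(tibble::tibble(day = -200, egfr = 80))))
  # closed interval at exactly -180 days
  expect_equal(select_baseline_egfr(tibble::tibble(day = -180, egfr = 88)), 88)
  expect_equal(select_baseline_egfr(tibble::tibble(day = c(-180, -170),
                                                   egfr = c(88, 91))), 91)
})


test_that("eligibility keeps compliant patients and logs first failing rule", {
  fx <- eligibility_fixture()
  out <- apply_eligibility(fx$patients, fx$labs)
  expect_equal(out$patients$patient_id, "OK")
  expect_equal(out$patients$year_of_start, 2006L)
  expect_equal(out$patients$baseline_egfr, 100, tolerance = 1e-6)
  reasons <- setNames(out$exclusions$reason, out$exclusions$patient_id)
  expect_equal(reasons[["EARLY"]], "pre_2004_start")
  expect_equal(reasons[["NOBASE"]], "no_baseline_creatinine")
  # baseline eGFR of exactly 60 fails the strict > 60 rule
  expect_equal(reasons[["LOWEGFR"]], "baseline_egfr_le_60")
  expect_equal(reasons[["ONEPOST"]], "fewer_than_2_post_start_creatinines")
  # fully compliant cohort passes through unchanged
  ok_only <- apply_eligibility(fx$patients[1, ],
                               fx$labs[fx$labs$patient_id == "OK", ])
  expect_equal(nrow(ok_only$exclusions), 0)
})

test_that("confirmed-CKD detection follows the 90-day sustained rule", {
  s <- function(day, egfr) tibble::tibble(day = day, egfr = egfr)
  ev <- detect_ckd_event(s(c(0.5, 100, 200), c(90, 55, 52)))
  expect_equal(ev$event_day, 100)
  expect_equal(ev$confirm_day, 200)
  # an intervening recovery voids the candidate under the strict rule
  broken <- s(c(0.5, 100, 130, 250), c(90, 55, 62, 52))
  expect_null(detect_ckd_event(broken))
  # ... but the relaxed flag confirms on any later sub-60 value 90+ days out
  relaxed <- detect_ckd_event(broken, any_later_confirm = TRUE)
  expect_equal(relaxed$event_day, 100)
  expect_equal(relaxed$confirm_day, 250)
  expect_null(detect_ckd_event(s(c(10, 120, 300), c(90, 75, 61))))
  # inserting extra sub-60 values between index and confirmation is neutral
  base <- s(c(10, 100, 200), c(90, 55, 52))
  extra <- s(c(10, 100, 140, 170, 200), c(90, 55, 58, 54, 52))
  expect_equal(detect_ckd_event(base), detect_ckd_event(extra))
  # confirmation needs >= 90 days, not almost 90
  expect_null(detect_ckd_event(s(c(10, 100, 189), c(90, 55, 52))))
  expect_equal(detect_ckd_event(s(c(10, 100, 190), c(90, 55, 52)))$confirm_day,
               190)
})

test_that("person-month expansion assigns events, switches and LVCF correctly", {
  p <- make_patients(patient_id = "A", baseline_egfr = 95,
                     year_of_start = 2006L)
  labs <- make_labs(p, c(-10, 100, 200), c(95, 55, 52))
  regs <- make_regimens(p, "TDF+FTC+EFV", 0, 730)
  events <- detect_ckd_events(ckdmsm:::add_lab_days(labs, p))
  pm <- expand_person_months(p, labs, regs, events)
  # event at day 100 lands in month 4 under the 30.44-day grid; nothing after
  expect_equal(nrow(pm), 4)
  expect_equal(pm$event, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(pm$on_initial))

  # 24 months, never switching, no event
  p2 <- make_patients(patient_id = "B", baseline_egfr = 95,
                      year_of_start = 2006L)
  labs2 <- make_labs(p2, c(-10, 100, 400), c(95, 96, 97))
  regs2 <- make_regimens(p2, "TDF+FTC+EFV", 0, 730)  # 730/30.44 -> 24 months
  pm2 <- expand_person_months(p2, labs2, regs2,
                              events = tibble::tibble(patient_id = character(0),
                                                      event_day = numeric(0),
                                                      confirm_day = numeric(0)))
  expect_equal(nrow(pm2), 24)
  expect_true(all(pm2$on_initial))
  expect_true(all(as.character(pm2$current_regimen) == "TDF_NNRTI"))

  # LVCF: eGFR 95 at baseline, 65 measured on day 100 -> category switches
  # at month 5 (first month whose start the new value precedes)
  labs3 <- make_labs(p2, c(-10, 100), c(95, 65))
  pm3 <- expand_person_months(p2, labs3, regs2,
                              events = tibble::tibble(patient_id = character(0),
                                                      event_day = numeric(0),
                                                      confirm_day = numeric(0)))
  expect_equal(as.character(pm3$egfr_cat[1:4]), rep(">90", 4))
  expect_equal(as.character(pm3$egfr_cat[5:24]), rep("51-70", 20))
})

test_that("switches flag the right month; within-type substitutions do not", {
  p <- make_patients(patient_id = "C", baseline_egfr = 95,
                     year_of_start = 2006L)
  labs <- make_labs(p, c(-10, 50, 300), c(95, 94, 93))
  regs <- tibble::tibble(
    patient_id = "C",
    start_date = p$art_start_date + c(0, 100),
    stop_date = p$art_start_date + c(100, 400),
    components = c("TDF+FTC+EFV", "ABC+3TC+NVP")
  )
  pm <- expand_person_months(p, labs, regs,
                             tibble::tibble(patient_id = character(0),
                                            event_day = numeric(0),
                                            confirm_day = numeric(0)))
  expect_equal(which(pm$switched_this_month), 4)  # day 100 is in month 4
  expect_equal(as.character(pm$current_regimen[4]), "TDF_NNRTI")
  expect_equal(as.character(pm$current_regimen[5]), "noTDF_NNRTI")
  expect_equal(as.character(pm$previous_regimen[5]), "TDF_NNRTI")
  expect_true(all(pm$on_initial[1:4]))
  expect_false(any(pm$on_initial[-(1:4)]))

  # same category on both sides of the substitution: no switch at all
  regs2 <- regs
  regs2$components <- c("TDF+FTC+EFV", "TDF+FTC+NVP")
  pm2 <- expand_person_months(p, labs, regs2,
                              tibble::tibble(patient_id = character(0),
                                             event_day = numeric(0),
                                             confirm_day = numeric(0)))
  expect_false(any(pm2$switched_this_month))
  expect_true(all(pm2$on_initial))
})

test_that("expansion conserves follow-up time and recovers every patient", {
  cfg <- sim_scenario("cohort", n_patients = 120, seed = 61,
                      dropout_hazard_monthly = 0)
  sim <- simulate_cohort(cfg)
  prep <- prepare_cohort(sim$patients, sim$labs, sim$regimens)
  expect_equal(nrow(prep$patients), 120)
  expect_equal(nrow(prep$exclusions), 0)

  pm <- prep$person_months
  counts <- dplyr::count(pm, .data$patient_id)
  # independent arithmetic: months = ceiling(terminal day / 30.44), with the
  # terminal day taken from the raw tables (event index day or regimen end)
  ends <- sim$regimens %>%
    dplyr::left_join(sim$patients %>% dplyr::select("patient_id", "art_start_date"),
                     by = "patient_id") %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(end = max(as.numeric(.data$stop_date - .data$art_start_date)))
  ev <- prep$events
  ends$end[match(ev$patient_id, ends$patient_id)] <- ev$event_day
  expected <- ceiling(ends$end / 30.44 - 1e-9)
  got <- counts$n[match(ends$patient_id, counts$patient_id)]
  expect_true(all(abs(got - expected) <= 1))
  expect_true(mean(got == expected) > 0.95)

  # months are contiguous 1..T and exactly one terminal state per patient
  contig <- pm %>% dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(ok = all(.data$month == seq_len(dplyr::n())))
  expect_true(all(contig$ok))
  # at most one terminal flag ends the on-initial stream, and at most one
  # event per patient overall
  term <- pm %>%
    dplyr::filter(.data$on_initial) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(
      n_events = sum(.data$event),
      last_flags = sum(.data$event[dplyr::n()],
                       .data$switched_this_month[dplyr::n()],
                       .data$censored_this_month[dplyr::n()])
    )
  expect_true(all(term$n_events <= 1))
  expect_true(all(term$last_flags <= 1))
  # every detected event appears as an event row
  expect_equal(sum(pm$event), nrow(prep$events))
})
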