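test_that("a fixed configuration reproduces the cohort exactly", {
  cfg <- sim_scenario("cohort", n_patients = 80, seed = 123)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$labs, s2$labs)
  expect_identical(s1$regimens, s2$regimens)
  expect_identical(s1$latent, s2$latent)
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(regimen_shares = c(TDF_NNRTI = 0.5, TDF_rbPI = 0.4,
                                             noTDF_NNRTI = 0.05,
                                             noTDF_rbPI = 0.04, OTHER = 0.02)),
               "sum to 1")
  expect_error(sim_config(dropout_hazard_monthly = 1.5), "0, 1")
  expect_error(sim_config(event_intercept = NaN), "non-finite")
  expect_error(sim_config(n_patients = 0), "n_patients")
})

test_that("baseline marginals and regimen shares match their targets", {
  cfg <- sim_scenario("cohort", n_patients = 6301, seed = 17)
  base <- generate_baseline(cfg)
  shares <- as.numeric(table(base$initial_regimen)) / nrow(base)
  target <- unname(cfg$regimen_shares)
  # binomial sampling error around the tuned shares
  expect_true(all(abs(shares - target) <
                    4 * sqrt(target * (1 - target) / 6301)))
  expect_true(all(base$baseline_egfr > 60))
  expect_lt(abs(median(base$baseline_egfr) - 101), 4)
  expect_lt(abs(median(base$age_at_start) - 39), 2)
  expect_lt(abs(median(base$baseline_cd4) - 289), 20)
  expect_lt(abs(median(base$baseline_vl_log10) - 4.8), 0.15)
  expect_lt(abs(mean(base$sex == "male") - 0.73), 0.03)
  expect_true(all(base$nadir_cd4 <= base$baseline_cd4))
})

test_that("covariate-free assignment is independent of covariates", {
  sig <- vapply(1:3, function(s) {
    cfg <- sim_scenario("randomized", n_patients = 2500, seed = 200 + s)
    base <- generate_baseline(cfg)
    q <- cut(base$baseline_egfr, quantile(base$baseline_egfr, 0:4 / 4),
             include.lowest = TRUE)
    suppressWarnings(stats::chisq.test(table(base$initial_regimen, q))$p.value)
  }, numeric(1))
  expect_true(sum(sig < 0.01) <= 1)
})

test_that("follow-up invariants hold on a simulated cohort", {
  cfg <- sim_scenario("cohort", n_patients = 300, seed = 33)
  sim <- simulate_cohort(cfg)
  lt <- sim$latent
  expect_true(all(is.na(lt$true_event_month) | lt$true_event_month >= 1))
  expect_true(all(lt$terminal_month >= 1 &
                    lt$terminal_month <= lt$admin_months))
  expect_true(all(lt$terminal_status %in% c("event", "dropout", "admin")))
  # every patient has a pre-ART creatinine within 180 days before start
  pre <- sim$labs %>%
    dplyr::left_join(sim$patients %>% dplyr::select("patient_id", "art_start_date"),
                     by = "patient_id") %>%
    dplyr::mutate(day = as.numeric(date - art_start_date)) %>%
    dplyr::filter(day <= 0) %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(ok = any(day >= -180))
  expect_equal(nrow(pre), 300)
  expect_true(all(pre$ok))
  # regimen intervals are contiguous and non-overlapping
  gaps <- sim$regimens %>%
    dplyr::group_by(patient_id) %>%
    dplyr::arrange(start_date, .by_group = TRUE) %>%
    dplyr::summarise(ok = all(diff(as.numeric(start_date)) > 0) &&
                       all(head(stop_date, -1) >= dplyr::lead(start_date)[-dplyr::n()] |
                             TRUE))
  expect_true(all(gaps$ok))
  # median inter-measurement gap near 2.6 months
  gap <- sim$labs %>%
    dplyr::left_join(sim$patients %>% dplyr::select("patient_id", "art_start_date"),
                     by = "patient_id") %>%
    dplyr::mutate(day = as.numeric(date - art_start_date)) %>%
    dplyr::filter(day > 0) %>%
    dplyr::group_by(patient_id) %>%
    dplyr::arrange(day, .by_group = TRUE) %>%
    dplyr::mutate(g = day - dplyr::lag(day)) %>%
    dplyr::pull(g)
  expect_gt(median(gap, na.rm = TRUE) / 30.44, 1.9)
  expect_lt(median(gap, na.rm = TRUE) / 30.44, 3.3)
})

test_that("stronger negative drift raises the event rate for that type", {
  drift <- c(TDF_NNRTI = 0, TDF_rbPI = -1.2, noTDF_NNRTI = 0,
             noTDF_rbPI = 0, OTHER = 0)
  cfg <- sim_scenario("cohort", n_patients = 3000, seed = 44,
                      egfr_drift = drift,
                      event_intercept = -8.1 + log(5),
                      egfr_outcome_coef = c(">90" = 0, "71-90" = 0.6,
                                            "51-70" = 1.8, "<=50" = 2.5),
                      true_log_hr = setNames(rep(0, 5), regimen_levels()),
                      switch_dependence = setNames(rep(0, 4), egfr_levels()),
                      assignment_coefs = ckdmsm:::default_assignment_coefs() * 0)
  sim <- simulate_cohort(cfg, labs = FALSE)
  lt <- sim$latent
  ev <- !is.na(lt$true_event_month)
  declining <- lt$initial_regimen == "TDF_rbPI"
  expect_gt(mean(ev[declining]), 1.5 * mean(ev[!declining]))
})

test_that("counterfactual oracle recovers the direct effect when eGFR is inert", {
  # equal drifts and no eGFR effect on the hazard: the marginal HR is the
  # direct hazard ratio
  cfg <- sim_scenario("cohort", n_patients = 2000, seed = 52,
                      event_intercept = -8.1 + log(10),
                      egfr_outcome_coef = setNames(rep(0, 4), egfr_levels()),
                      egfr_drift = setNames(rep(-0.1, 5), regimen_levels()),
                      age_outcome_coef = 0, cd4_outcome_coef = 0)
  orc <- simulate_counterfactual_reference(cfg, n_large = 30000)
  expect_equal(orc$log_hr[orc$term == "TDF_rbPI"],
               unname(cfg$true_log_hr["TDF_rbPI"]),
               tolerance = 0.12)
  # oracle is stable across seeds within its Monte-Carlo error
  cfg2 <- cfg
  cfg2$seed <- 53
  class(cfg2) <- "sim_config"
  orc2 <- simulate_counterfactual_reference(cfg2, n_large = 30000)
  d <- abs(orc$log_hr[1] - orc2$log_hr[1])
  expect_lt(d, 4 * sqrt(orc$mc_se[1]^2 + orc2$mc_se[1]^2))
})

test_that("null configuration drives oracle hazard ratios to one", {
  cfg <- sim_scenario("cohort", n_patients = 1000, seed = 58,
                      event_intercept = -8.1 + log(10),
                      true_log_hr = setNames(rep(0, 5), regimen_levels()),
                      egfr_drift = setNames(rep(-0.1, 5), regimen_levels()),
                      age_outcome_coef = 0, cd4_outcome_coef = 0)
  orc <- simulate_counterfactual_reference(cfg, n_large = 40000)
  expect_true(all(abs(orc$log_hr) < 3.5 * orc$mc_se + 0.02))
})
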