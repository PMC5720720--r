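test_that("baseline table reproduces hand-computed medians and counts", {
  pts <- make_patients(n = 4)
  pts$age_at_start <- c(30, 40, 50, 60)
  pts$baseline_egfr <- c(80, 90, 100, 110)
  pts$baseline_cd4 <- c(100, 200, 300, 400)
  pts$baseline_vl_log10 <- c(4, 4.5, 5, 5.5)
  pts$nadir_cd4 <- c(90, 180, 270, 360)
  pts$sex <- c("male", "male", "female", "male")
  pts$initial_regimen <- regimen_factor(c("TDF_rbPI", "TDF_rbPI",
                                          "TDF_NNRTI", "TDF_NNRTI"))
  tab <- make_baseline_table(pts)
  expect_equal(tab$All[tab$variable == "n"], "4")
  expect_equal(tab$All[tab$variable == "age"], "45 (38-52)")
  expect_equal(tab$TDF_rbPI[tab$variable == "age"], "35 (32-38)")
  expect_equal(tab$All[tab$variable == "male"], "3 (75)")
  expect_equal(tab$TDF_NNRTI[tab$variable == "male"], "1 (50)")

  # single-category cohort: the by-type column equals the overall column
  solo <- pts %>% dplyr::mutate(initial_regimen = regimen_factor("TDF_rbPI"))
  tab2 <- make_baseline_table(solo)
  expect_equal(tab2$TDF_rbPI, tab2$All)
})

test_that("cohort files round-trip and contain no latent columns", {
  cfg <- sim_scenario("cohort", n_patients = 40, seed = 7)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, with_oracle = TRUE)
  expect_setequal(list.files(dir),
                  c("patients.csv", "labs.csv", "regimens.csv", "oracle.csv"))
  back <- read_cohort(dir)
  expect_equal(nrow(back$patients), 40)
  leak <- c("true_event_month", "terminal_status", "first_switch_month",
            "baseline_egfr", "initial_regimen")
  expect_false(any(leak %in% names(back$patients)))
  expect_false(any(leak %in% names(back$labs)))
  expect_false(any(leak %in% names(back$regimens)))
  # values survive the round trip (dates, creatinine precision)
  expect_equal(back$labs$scr, sim$labs$scr)
  expect_equal(back$regimens$start_date, sim$regimens$start_date)
  # prepared analysis matches whether it starts from memory or from disk
  p1 <- prepare_cohort(sim$patients, sim$labs, sim$regimens)
  p2 <- prepare_cohort(back$patients, back$labs, back$regimens)
  expect_equal(p1$person_months$event, p2$person_months$event)
  expect_equal(as.character(p1$person_months$egfr_cat),
               as.character(p2$person_months$egfr_cat))
})

test_that("pipeline runs end to end, deterministically, with stage toggles", {
  cfg <- sim_scenario("cohort", n_patients = 300, seed = 19)
  rep1 <- suppressWarnings(suppressMessages(
    run_pipeline(cfg, stages = c("traditional", "discontinuation"))))
  expect_s3_class(rep1, "ckd_report")
  expect_null(rep1$causal)
  expect_true(all(c("initial", "current", "current_plus_previous") %in%
                    rep1$traditional$model))
  expect_true(nrow(rep1$discontinuation) > 0)
  expect_true(all(is.finite(rep1$incidence$rate_per_1000py)))

  rep2 <- suppressWarnings(suppressMessages(
    run_pipeline(cfg, stages = c("traditional", "discontinuation"))))
  expect_equal(rep1$traditional$estimate, rep2$traditional$estimate)
  expect_equal(rep1$incidence, rep2$incidence)

  # percentages per categorical row parse and lie in [0, 100]
  pct <- as.numeric(sub(".*\\((\\d+)\\).*", "\\1",
                        rep1$baseline_table$All[rep1$baseline_table$statistic == "n (%)"]))
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("tidy and glance give broom-shaped output", {
  pm <- make_pm_cohort(c(5, 8, 11, 14), c(TRUE, TRUE, FALSE, TRUE),
                       c("TDF_rbPI", "TDF_NNRTI", "TDF_rbPI", "TDF_NNRTI"))
  f <- fit_msm(pm, estimator = "crude")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "robust_se", "hr", "conf_low",
                    "conf_high", "p_value") %in% names(td)))
  expect_equal(td$hr, exp(td$estimate))
  g <- glance(f)
  expect_equal(nrow(g), 1)
  expect_equal(g$model, "crude")
})

test_that("plot builders return ggplot objects", {
  w <- tibble::tibble(patient_id = rep("A", 12), month = rep(1:6, 2),
                      sw_t = exp(rnorm(12, 0, 0.2)))
  expect_s3_class(autoplot(weight_diagnostics(w)), "ggplot")
  irr <- tibble::tibble(regimen = "TDF_rbPI", egfr_cat = c("71-90", "51-70"),
                        irr = c(1.5, 3), conf_low = c(1, 2),
                        conf_high = c(2.2, 4.5))
  expect_s3_class(plot_switch_irr(irr), "ggplot")
})
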