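test_that("covariate-free treatment model gives unit baseline weights", {
  set.seed(5)
  pts <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:400),
    initial_regimen = sample(regimen_levels(), 400, TRUE,
                             prob = c(0.2, 0.35, 0.05, 0.25, 0.15))
  )
  out <- fit_baseline_treatment_model(pts, formula = initial_regimen ~ 1)
  expect_equal(out$sw_a$sw_a, rep(1, 400), tolerance = 1e-6)
})

test_that("saturated multinomial fit matches closed-form cell proportions", {
  # two categories x one binary covariate: the MLE is the empirical
  # conditional proportion in each cell
  pts <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:60),
    x = rep(c(0, 1), each = 30),
    initial_regimen = c(rep(c("TDF_NNRTI", "TDF_rbPI"), c(10, 20)),
                        rep(c("TDF_NNRTI", "TDF_rbPI"), c(21, 9)))
  )
  out <- fit_baseline_treatment_model(pts, formula = initial_regimen ~ x)
  d <- out$sw_a
  p_obs <- ifelse(pts$x == 0,
                  ifelse(pts$initial_regimen == "TDF_NNRTI", 10 / 30, 20 / 30),
                  ifelse(pts$initial_regimen == "TDF_NNRTI", 21 / 30, 9 / 30))
  marg <- ifelse(pts$initial_regimen == "TDF_NNRTI", 31 / 60, 29 / 60)
  expect_equal(d$denominator, p_obs, tolerance = 1e-9)
  expect_equal(d$sw_a, marg / p_obs, tolerance = 1e-9)
})

test_that("randomized assignment yields baseline weights concentrating at 1", {
  cfg <- sim_scenario("randomized", n_patients = 1500, seed = 81)
  base <- generate_baseline(cfg)
  out <- fit_baseline_treatment_model(base)
  expect_lt(abs(mean(out$sw_a$sw_a) - 1), 0.05)
  expect_lt(sd(out$sw_a$sw_a), 0.25)
})

test_that("saturated pooled logistic fit reproduces empirical cell hazards", {
  set.seed(9)
  n <- 500
  pm <- make_pm_cohort(rep(4, n), rep(FALSE, n),
                       sample(c("TDF_NNRTI", "TDF_rbPI"), n, TRUE))
  pm$xbin <- rep(rep(c(0, 1), each = 2), n)   # varies within follow-up
  p_true <- ifelse(pm$xbin == 1, 0.15, 0.05)
  pm$switched_this_month <- runif(nrow(pm)) < p_true
  pm$censored_this_month <- FALSE
  sc <- fit_switch_and_censor_models(
    pm, stratify = "none",
    formula_den = ~xbin, formula_num = ~xbin, glm_epsilon = 1e-12
  )
  cells <- tapply(pm$switched_this_month, pm$xbin, mean)
  got <- 1 - sc$probabilities$den_switch
  expect_equal(unname(got[pm$xbin == 0][1]), unname(cells["0"]),
               tolerance = 1e-9)
  expect_equal(unname(got[pm$xbin == 1][1]), unname(cells["1"]),
               tolerance = 1e-9)
})

test_that("stabilized weight products follow the cumulative definition", {
  sw_a <- tibble::tibble(patient_id = "A", sw_a = 1)
  probs <- tibble::tibble(
    patient_id = "A", month = 1:2,
    num_switch = c(0.98, 0.99), den_switch = c(0.95, 0.97),
    num_cens = c(1, 1), den_cens = c(1, 1)
  )
  w <- compute_stabilized_weights(sw_a, probs)
  expect_equal(w$sw_t[1], 0.98 / 0.95, tolerance = 1e-12)
  expect_equal(w$sw_t[2], (0.98 * 0.99) / (0.95 * 0.97), tolerance = 1e-12)

  # numerator == denominator collapses SW(t) to 1
  probs_eq <- probs %>% dplyr::mutate(num_switch = den_switch,
                                      num_cens = den_cens)
  expect_equal(compute_stabilized_weights(sw_a, probs_eq)$sw_t, c(1, 1))

  # invalid denominators are named, not silently propagated
  probs_bad <- probs
  probs_bad$den_cens[2] <- 0
  expect_error(compute_stabilized_weights(sw_a, probs_bad), "month 2")

  # symmetric percentile truncation clips the tails
  sw_many <- tibble::tibble(patient_id = sprintf("P%02d", 1:50), sw_a = 1)
  probs_many <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:50), month = 1,
    num_switch = seq(0.5, 0.99, length.out = 50), den_switch = 0.9,
    num_cens = 1, den_cens = 1
  )
  wt <- compute_stabilized_weights(sw_many, probs_many,
                                   truncate_quantiles = c(0.1, 0.9))
  w0 <- compute_stabilized_weights(sw_many, probs_many)
  expect_equal(min(wt$sw_t), unname(quantile(w0$sw_t, 0.1)))
  expect_equal(max(wt$sw_t), unname(quantile(w0$sw_t, 0.9)))
})

test_that("weight diagnostics agree with direct computation", {
  w1 <- tibble::tibble(patient_id = "A", month = 1:5, sw_a = 1,
                       num_switch = 1, den_switch = 1, num_cens = 1,
                       den_cens = 1, sw_t = 1)
  d1 <- weight_diagnostics(w1)
  expect_equal(d1$summary$mean, 1)
  expect_equal(d1$summary$sd, 0)

  set.seed(3)
  w2 <- tibble::tibble(patient_id = rep(sprintf("P%02d", 1:20), each = 6),
                       month = rep(1:6, 20), sw_t = exp(rnorm(120, 0, 0.3)))
  d2 <- weight_diagnostics(w2)
  expect_equal(d2$summary$mean, mean(w2$sw_t), tolerance = 1e-12)
  expect_equal(d2$summary$sd, sd(w2$sw_t), tolerance = 1e-12)
  expect_equal(d2$summary$max, max(w2$sw_t))
  # the listed extreme is the true extreme row
  i <- which.max(abs(log(w2$sw_t)))
  expect_equal(d2$extremes$sw_t[1], w2$sw_t[i])
  expect_equal(nrow(d2$by_month), 6)
})

test_that("weights average near one under correct specification", {
  cfg <- sim_scenario("cohort", n_patients = 900, seed = 37)
  sim <- simulate_cohort(cfg)
  prep <- prepare_cohort(sim$patients, sim$labs, sim$regimens)
  w <- suppressWarnings(suppressMessages(estimate_weights(prep$person_months)))
  expect_gt(w$diagnostics$summary$mean, 0.9)
  expect_lt(w$diagnostics$summary$mean, 1.1)
  # monthly means stay near one too (no systematic drift over follow-up)
  bm <- w$diagnostics$by_month %>% dplyr::filter(.data$n >= 100)
  expect_lt(max(abs(bm$mean - 1)), 0.25)
})
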