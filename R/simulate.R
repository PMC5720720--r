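r_trunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  lo <- stats::plnorm(lower, meanlog, sdlog)
  hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(runif(n, lo, hi), meanlog, sdlog)
}

r_trunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Generate baseline patient characteristics
#'
#' Draws `n_patients` baseline rows: demographics and laboratory covariates
#' from truncated (log-)normal distributions matched to the calibration
#' medians/IQRs, comorbidity flags from Bernoulli prevalences, ART start
#' dates uniform over the accrual window, and the initial regimen type from a
#' polytomous logistic model on standardised baseline covariates whose
#' intercepts are tuned (iterative proportional fitting on the realised
#' covariates) so marginal shares match `regimen_shares`. All baseline eGFR
#' values exceed 60 ml/min/1.73m2.
#'
#' @param config a [sim_config()].
#' @return Tibble, one row per patient, including `baseline_egfr` and
#'   `initial_regimen` (used downstream by the simulator; dropped from
#'   exported analysis files by [write_cohort()]).
#' @export
generate_baseline <- function(config) {
  validate_sim_config(config)
  bm <- config$baseline_marginals
  n <- config$n_patients
  set.seed(config$seed)

  age <- round(r_trunc_lnorm(n, bm$age$meanlog, bm$age$sdlog,
                             bm$age$lower, bm$age$upper), 1)
  sex <- ifelse(runif(n) < bm$p_male, "male", "female")
  hiv_exposure <- names(bm$exposure_probs)[
    1 + rowSums(runif(n) > matrix(cumsum(bm$exposure_probs)[-3], n, 2, byrow = TRUE))]
  cd4 <- round(r_trunc_lnorm(n, bm$cd4$meanlog, bm$cd4$sdlog,
                             bm$cd4$lower, bm$cd4$upper))
  nadir <- round(cd4 * runif(n, bm$nadir_frac$lower, bm$nadir_frac$upper))
  vl <- round(r_trunc_norm(n, bm$vl_log10$mean, bm$vl_log10$sd,
                           bm$vl_log10$lower, bm$vl_log10$upper), 2)
  egfr <- round(r_trunc_lnorm(n, bm$egfr$meanlog, bm$egfr$sdlog,
                              bm$egfr$lower, bm$egfr$upper), 1)
  entry0 <- as.Date(bm$entry_start)
  entry1 <- as.Date(bm$entry_end)
  art_start <- entry0 + floor(runif(n, 0, as.numeric(entry1 - entry0) + 1))

  # polytomous assignment with intercepts tuned to the target shares; the
  # covariate marginals are truncated, so the linear logits stay bounded and
  # a linear polytomous weight model is correctly specified
  X <- cbind(
    z_age = (age - 39) / 10,
    z_nadir = (nadir - 264) / 150,
    z_cd4 = (cd4 - 289) / 150,
    z_vl = (vl - 4.8) / 0.8,
    z_egfr = (egfr - 101) / 25
  )
  eta0 <- X %*% config$assignment_coefs
  alpha <- log(config$regimen_shares)
  for (it in 1:60) {
    p <- softmax_rows(sweep(eta0, 2, alpha, "+"))
    alpha <- alpha + log(config$regimen_shares) - log(colMeans(p))
  }
  p <- softmax_rows(sweep(eta0, 2, alpha, "+"))
  u <- runif(n)
  cum <- t(apply(p, 1, cumsum))
  reg_idx <- 1L + rowSums(u > cum[, -5, drop = FALSE])
  initial_regimen <- regimen_factor(regimen_levels()[reg_idx])

  tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    art_start_date = art_start,
    age_at_start = age,
    sex = sex,
    hiv_exposure = hiv_exposure,
    nadir_cd4 = nadir,
    baseline_cd4 = cd4,
    baseline_vl_log10 = vl,
    baseline_egfr = egfr,
    hbv = runif(n) < bm$p_hbv,
    hcv = runif(n) < bm$p_hcv,
    diabetes = runif(n) < bm$p_diabetes,
    hypertension = runif(n) < bm$p_hypertension,
    cvd = runif(n) < bm$p_cvd,
    initial_regimen = initial_regimen
  )
}

# post-switch destination matrix (rows: from, cols: to); a switch always
# changes category
switch_transition_matrix <- function(config) {
  lv <- regimen_levels()
  tm <- matrix(0, 5, 5, dimnames = list(lv, lv))
  counterpart <- c(TDF_NNRTI = "noTDF_NNRTI", TDF_rbPI = "noTDF_rbPI")
  for (g in lv) {
    rest <- setdiff(lv, g)
    if (g %in% names(counterpart)) {
      tm[g, counterpart[g]] <- config$tdf_counterpart_prob
      tm[g, "OTHER"] <- config$other_switch_prob
      even <- setdiff(rest, c(counterpart[g], "OTHER"))
      tm[g, even] <- (1 - config$tdf_counterpart_prob - config$other_switch_prob) /
        length(even)
    } else if (g != "OTHER") {
      tm[g, "OTHER"] <- config$other_switch_prob
      even <- setdiff(rest, "OTHER")
      tm[g, even] <- (1 - config$other_switch_prob) / length(even)
    } else {
      tm[g, rest] <- 1 / length(rest)
    }
  }
  tm
}

# representative drug combinations per regimen type, so the exported
# regimen-interval file carries component strings the classifier can parse
regimen_components <- function() {
  c(TDF_NNRTI = "TDF+FTC+EFV", TDF_rbPI = "TDF+FTC+DRV+RTV",
    noTDF_NNRTI = "ABC+3TC+NVP", noTDF_rbPI = "ABC+3TC+LPV+RTV",
    OTHER = "TDF+FTC+RAL")
}

#' Simulate longitudinal follow-up for a baseline cohort
#'
#' Monthly latent eGFR evolves as a random walk with regimen-dependent drift,
#' reflected just above 60 so the discrete-time hazard is the only event
#' pathway. Each month the event indicator is drawn from
#' `exp(event_intercept + true_log_hr[regimen] + egfr_outcome_coef[latent
#' category])`; switching away from the current regimen follows a logistic
#' model in the last *observed* eGFR category (treatment-confounder
#' feedback), with the destination drawn from a fixed transition matrix;
#' dropout and administrative censoring close follow-up. Laboratory values
#' are point samples of the latent state at log-normally spaced visit times
#' (median gap ~2.6 months, plus guaranteed month-1 and month-2 visits and a
#' pre-ART baseline measurement). A hazard event forces a sub-60 laboratory
#' pair (index value plus confirmation `confirm_gap_days` later) so the
#' confirmed-CKD detector recovers the event from exported files.
#'
#' @param baseline tibble from [generate_baseline()].
#' @param config the same [sim_config()].
#' @param labs generate laboratory data (disable for large counterfactual
#'   runs).
#' @param disable_switching,disable_dropout switch off those processes
#'   (counterfactual oracle mode).
#' @param full_followup give every patient the administrative maximum
#'   follow-up instead of entry-date-dependent censoring.
#' @param keep_trajectories attach the latent monthly eGFR matrix to the
#'   result (`attr(latent, "egfr_trajectories")`).
#' @return List of class `sim_cohort` with `patients`, `labs`, `regimens`
#'   (analysis files) and `latent` (oracle-only truth: true event month,
#'   terminal status, first switch month).
#' @export
simulate_followup <- function(baseline, config, labs = TRUE,
                              disable_switching = FALSE,
                              disable_dropout = FALSE,
                              full_followup = FALSE,
                              keep_trajectories = FALSE) {
  validate_sim_config(config)
  n <- nrow(baseline)
  md <- MONTH_DAYS
  bm <- config$baseline_marginals
  set.seed(config$seed + 1L)

  close <- as.Date(bm$close_date)
  admin <- pmin(config$followup_max_months,
                floor(as.numeric(close - baseline$art_start_date) / md))
  if (isTRUE(full_followup)) admin <- rep(config$followup_max_months, n)
  admin <- pmax(admin, 1L)
  tmax <- max(admin)

  reg <- as.integer(baseline$initial_regimen)
  drift <- unname(config$egfr_drift)
  loghr <- unname(config$true_log_hr)
  # fixed baseline frailty contribution to the monthly log-hazard
  hz_base <- (config$age_outcome_coef %||% 0) *
    (baseline$age_at_start - 39) / 10 +
    (config$cd4_outcome_coef %||% 0) * (baseline$baseline_cd4 - 289) / 150
  gcoef <- unname(config$egfr_outcome_coef)
  swdep <- unname(config$switch_dependence)
  swoff <- unname(config$switch_regimen_offset[regimen_levels()])
  tdf_reg <- c(TRUE, TRUE, FALSE, FALSE, FALSE)  # regimen_levels() order
  tmat <- switch_transition_matrix(config)
  cum_tmat <- t(apply(tmat, 1, cumsum))

  # pre-drawn laboratory visit months
  L <- NULL
  if (isTRUE(labs)) {
    K <- max(30L, ceiling(tmax * 0.9))
    gaps <- matrix(pmin(pmax(rlnorm(n * K, config$lab_gap_meanlog,
                                    config$lab_gap_sdlog), 0.3),
                        config$lab_gap_cap), n, K)
    tm_cum <- gaps
    for (k in 2:K) tm_cum[, k] <- tm_cum[, k - 1] + gaps[, k]
    mwhen <- ceiling(tm_cum)
    L <- matrix(FALSE, n, tmax)
    sel <- which(mwhen <= tmax)
    L[cbind(((sel - 1) %% n) + 1, mwhen[sel])] <- TRUE
    L[, 1] <- TRUE
    if (tmax >= 2) L[, 2] <- TRUE
  }

  egfr <- baseline$baseline_egfr
  obs_egfr <- baseline$baseline_egfr
  active <- rep(TRUE, n)
  term_month <- admin
  status <- rep("admin", n)
  event_month <- rep(NA_integer_, n)
  E <- matrix(NA_real_, n, tmax)
  sw_pid <- integer(0); sw_day <- numeric(0); sw_to <- integer(0)
  egfr_cut <- c(-Inf, 50, 70, 90, Inf)  # index 4 = ">90" ... 1 = "<=50"

  for (t in seq_len(tmax)) {
    idx <- which(active)
    if (length(idx) == 0) break
    egfr[idx] <- pmax(egfr[idx] + drift[reg[idx]] +
                        rnorm(length(idx), 0, config$egfr_noise_sd),
                      config$egfr_floor)
    E[idx, t] <- egfr[idx]

    # event draw from the discrete-time hazard (latent eGFR category)
    cat_lat <- 5L - findInterval(egfr[idx], egfr_cut[2:4]) - 1L
    # map: egfr>90 -> 1, 71-90 -> 2, 51-70 -> 3, <=50 -> 4
    h <- exp(config$event_intercept + loghr[reg[idx]] + gcoef[cat_lat] +
               hz_base[idx])
    ev <- runif(length(idx)) < pmin(h, 0.9)
    if (any(ev)) {
      ei <- idx[ev]
      event_month[ei] <- t
      term_month[ei] <- t
      status[ei] <- "event"
      active[ei] <- FALSE
    }

    # switch draw from the observed (last measured) eGFR category
    idx2 <- idx[!ev]
    if (!disable_switching && length(idx2) > 0) {
      cat_obs <- 5L - findInterval(obs_egfr[idx2], egfr_cut[2:4]) - 1L
      dep <- swdep[cat_obs]
      if (isTRUE(config$switch_tdf_only)) dep <- dep * tdf_reg[reg[idx2]]
      psw <- plogis(config$switch_intercept + swoff[reg[idx2]] + dep)
      sw <- runif(length(idx2)) < psw
      if (any(sw)) {
        si <- idx2[sw]
        u <- runif(length(si))
        new_reg <- 1L + rowSums(matrix(u, length(si), 5) >
                                  cum_tmat[reg[si], , drop = FALSE])
        day <- ceiling((t - 1) * md + 1 + runif(length(si)) * (md - 2.5))
        sw_pid <- c(sw_pid, si); sw_day <- c(sw_day, day)
        sw_to <- c(sw_to, new_reg)
        reg[si] <- new_reg
      }
    }

    # dropout, then administrative end
    idx3 <- idx2[active[idx2]]
    if (!disable_dropout && config$dropout_hazard_monthly > 0 &&
        length(idx3) > 0) {
      dr <- runif(length(idx3)) < config$dropout_hazard_monthly
      if (any(dr)) {
        di <- idx3[dr]
        term_month[di] <- t
        status[di] <- "dropout"
        active[di] <- FALSE
      }
    }
    fin <- which(active & admin == t)
    if (length(fin) > 0) {
      term_month[fin] <- t
      status[fin] <- "admin"
      active[fin] <- FALSE
    }

    # labs measured this month become available from next month on
    if (!is.null(L)) {
      has <- which(L[, t] & !is.na(E[, t]))
      if (length(has) > 0) obs_egfr[has] <- E[has, t]
    }
  }

  # terminal day bookkeeping
  ev_day <- ifelse(status == "event",
                   floor((term_month - 1) * md + 14), NA_real_)
  end_day <- ifelse(status == "event", ev_day + config$confirm_gap_days,
                    floor(term_month * md))

  # regimen intervals from the switch log
  init_int <- tibble(pid = seq_len(n), start_day = 0,
                     reg = as.integer(baseline$initial_regimen))
  sw_int <- tibble(pid = sw_pid, start_day = sw_day, reg = sw_to)
  intervals <- bind_rows(init_int, sw_int) %>%
    arrange(.data$pid, .data$start_day) %>%
    filter(.data$start_day < end_day[.data$pid]) %>%
    group_by(.data$pid) %>%
    mutate(stop_day = dplyr::lead(.data$start_day, default = Inf)) %>%
    ungroup() %>%
    mutate(stop_day = pmin(.data$stop_day, end_day[.data$pid]))
  regimens <- intervals %>%
    transmute(
      patient_id = baseline$patient_id[.data$pid],
      start_date = baseline$art_start_date[.data$pid] + .data$start_day,
      stop_date = baseline$art_start_date[.data$pid] + ceiling(.data$stop_day),
      components = unname(regimen_components()[regimen_levels()[.data$reg]])
    )

  lab_tbl <- NULL
  if (!is.null(L)) {
    lab_idx <- which(L, arr.ind = TRUE)
    li <- tibble(pid = lab_idx[, 1], month = lab_idx[, 2]) %>%
      filter(.data$month <= term_month[.data$pid] -
               (status[.data$pid] == "event")) %>%
      mutate(
        day = ceiling((.data$month - 1) * md + 1 + runif(dplyr::n()) * (md - 2.5)),
        egfr = E[cbind(.data$pid, .data$month)]
      ) %>%
      filter(!is.na(.data$egfr))
    # pre-ART baseline measurement (always within the 180-day window)
    pre <- tibble(pid = seq_len(n), month = 0L,
                  day = -sample(5:175, n, replace = TRUE),
                  egfr = baseline$baseline_egfr)
    # forced event + confirmation pair
    evp <- which(status == "event")
    forced <- tibble(
      pid = rep(evp, 2),
      month = rep(term_month[evp], 2),
      day = c(ev_day[evp], ev_day[evp] + config$confirm_gap_days),
      egfr = pmin(rep(c(55, 53), each = length(evp)) -
                    stats::rnorm(2 * length(evp), 0, 1), 58.5)
    )
    all_labs <- bind_rows(pre, li, forced) %>%
      mutate(
        age_at = baseline$age_at_start[.data$pid] + .data$day / 365.25,
        scr = round(scr_from_egfr(.data$egfr, .data$age_at,
                                  baseline$sex[.data$pid]), 2),
        cd4 = pmax(5, round(baseline$baseline_cd4[.data$pid] +
                              config$cd4_recovery_rate * pmin(pmax(.data$month, 0), 48) +
                              rnorm(dplyr::n(), 0, 25))),
        vl_log = pmax(1.3, baseline$baseline_vl_log10[.data$pid] -
                        config$vl_decay_rate * pmax(.data$month, 0) +
                        rnorm(dplyr::n(), 0, 0.15)),
        vl = round(10^.data$vl_log)
      )
    lab_tbl <- all_labs %>%
      transmute(
        patient_id = baseline$patient_id[.data$pid],
        date = baseline$art_start_date[.data$pid] + .data$day,
        scr = .data$scr, cd4 = .data$cd4, vl = .data$vl
      ) %>%
      arrange(.data$patient_id, .data$date)
  }

  first_sw <- rep(NA_integer_, n)
  if (length(sw_pid) > 0) {
    fs <- tapply(sw_day, sw_pid, min)
    first_sw[as.integer(names(fs))] <-
      as.integer(ceiling(unname(fs) / md - 1e-9))
  }
  latent <- tibble(
    patient_id = baseline$patient_id,
    initial_regimen = baseline$initial_regimen,
    true_event_month = event_month,
    terminal_month = term_month,
    terminal_status = status,
    admin_months = admin,
    first_switch_month = first_sw
  )
  if (isTRUE(keep_trajectories)) attr(latent, "egfr_trajectories") <- E

  structure(list(patients = baseline, labs = lab_tbl, regimens = regimens,
                 latent = latent),
            class = "sim_cohort")
}

#' Simulate a complete synthetic cohort
#'
#' [generate_baseline()] followed by [simulate_followup()].
#'
#' @inheritParams simulate_followup
#' @inheritParams generate_baseline
#' @param ... passed to [simulate_followup()].
#' @return A `sim_cohort` list (see [simulate_followup()]).
#' @export
simulate_cohort <- function(config, ...) {
  simulate_followup(generate_baseline(config), config, ...)
}

#' Counterfactual oracle: true marginal hazard ratios
#'
#' Re-runs the simulator with switching and dropout disabled (everyone stays
#' on the initial regimen), then fits an unadjusted proportional hazards
#' model of the *true* event month on the initial regimen type at large `n`.
#' The resulting hazard ratios are the sustained-treatment marginal effects
#' the weighted analysis is meant to recover; they include both the direct
#' regimen effect and the drift-mediated eGFR pathway.
#'
#' By default the oracle keeps the study's censoring structure — the
#' entry-dependent administrative schedule and non-informative dropout —
#' because the drift pathway makes the marginal hazard ratio
#' horizon-dependent: stabilized weights balance covariates across switching
#' and dropout but do not extend anyone's follow-up, so the weighted
#' analysis targets the no-switching world *under the study's censoring*.
#' `keep_dropout = FALSE` and/or `full_followup = TRUE` give the fully
#' uncensored counterfactual instead.
#'
#' @param config a [sim_config()]; only its structural parameters are used.
#' @param n_large number of counterfactual patients.
#' @param keep_dropout retain the study's (non-informative) dropout process.
#' @param full_followup follow everyone to `followup_max_months` rather than
#'   the entry-dependent administrative schedule.
#' @return Tibble with `term`, `log_hr`, `hr` and `mc_se` (Monte-Carlo
#'   standard error of the log HR); reference level `TDF_NNRTI`.
#' @export
simulate_counterfactual_reference <- function(config, n_large = 50000,
                                              keep_dropout = TRUE,
                                              full_followup = FALSE) {
  cfg <- config
  cfg$n_patients <- n_large
  cfg$seed <- (config$seed * 31L + 1047L) %% 2000000000L
  # the marginal ("randomized-trial") effect: assignment independent of
  # covariates, shares kept at the study's marginal shares
  cfg$assignment_coefs <- cfg$assignment_coefs * 0
  class(cfg) <- "sim_config"
  base <- generate_baseline(cfg)
  fu <- simulate_followup(base, cfg, labs = FALSE, disable_switching = TRUE,
                          disable_dropout = !keep_dropout,
                          full_followup = full_followup)
  lt <- fu$latent
  time <- ifelse(is.na(lt$true_event_month), lt$terminal_month,
                 lt$true_event_month)
  ev <- !is.na(lt$true_event_month)
  fit <- survival::coxph(
    survival::Surv(time, ev) ~ initial_regimen,
    data = tibble(time = time, ev = ev, initial_regimen = lt$initial_regimen),
    ties = "efron"
  )
  se <- sqrt(diag(vcov(fit)))
  if (n_large < 5000 || any(se > 0.15)) {
    warning("counterfactual oracle may be unstable at this n; ",
            "largest Monte-Carlo SE = ", signif(max(se), 3), call. = FALSE)
  }
  tibble(
    term = sub("^initial_regimen", "", names(coef(fit))),
    log_hr = unname(coef(fit)),
    hr = exp(unname(coef(fit))),
    mc_se = unname(se)
  )
}
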