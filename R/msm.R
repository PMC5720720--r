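#' Crude, adjusted, weighted and doubly robust on-initial-regimen models
#'
#' The second analysis series: proportional hazards fits on person-month
#' counting-process data restricted to follow-up on the initial regimen type
#' (patients are censored upon any change of type). Four estimators:
#'
#' * `crude` — unweighted, covariate-free fit on the initial-regimen
#'   indicators;
#' * `adjusted` — adds the baseline confounders and time-varying CD4 /
#'   viral-load categories;
#' * `weighted` — the marginal structural model: covariate-free fit weighted
#'   by the stabilized weights SW(t);
#' * `doubly_robust` — the SW(t)-weighted fit *with* the adjusted covariate
#'   set, consistent if either the weight models or the outcome model are
#'   correct.
#'
#' All variants report patient-clustered sandwich (robust) standard errors.
#' Weights are normalised to mean one before fitting (point estimates are
#' invariant to positive rescaling).
#'
#' @param person_months person-month tibble; only `on_initial` rows are used.
#' @param weights WeightSet tibble from [compute_stabilized_weights()] /
#'   [estimate_weights()]; required for `weighted` and `doubly_robust` and
#'   it must cover every analysed person-month.
#' @param estimator one of `"crude"`, `"adjusted"`, `"weighted"`,
#'   `"doubly_robust"`.
#' @param reference reference regimen type.
#' @param robust compute patient-clustered sandwich standard errors
#'   (default); `FALSE` reports model-based SEs only, which is faster when a
#'   simulation study only needs the point estimate.
#' @return A `ckd_fit`.
#' @export
fit_msm <- function(person_months, weights = NULL,
                    estimator = c("crude", "adjusted", "weighted",
                                  "doubly_robust"),
                    reference = "TDF_NNRTI", robust = TRUE) {
  estimator <- match.arg(estimator)
  d <- person_months %>% filter(.data$on_initial)
  d$exposure_initial <- stats::relevel(regimen_factor(d$initial_regimen),
                                       ref = reference)

  w <- NULL
  if (estimator %in% c("weighted", "doubly_robust")) {
    if (is.null(weights)) {
      stop("`weights` are required for the ", estimator, " estimator",
           call. = FALSE)
    }
    d <- d %>% left_join(weights %>% select("patient_id", "month", "sw_t"),
                         by = c("patient_id", "month"))
    if (any(is.na(d$sw_t))) {
      stop(sum(is.na(d$sw_t)),
           " analysed person-month(s) lack a stabilized weight", call. = FALSE)
    }
    if (any(d$sw_t <= 0)) stop("nonpositive weight", call. = FALSE)
    w <- d$sw_t / mean(d$sw_t)
    d$.w <- w
  }

  rhs <- "exposure_initial"
  if (estimator %in% c("adjusted", "doubly_robust")) {
    rhs <- c(rhs, baseline_covariates(), tv_covariates())
  }
  f <- reformulate(rhs, response = "survival::Surv(tstart, tstop, event)")
  fit <- if (isTRUE(robust)) {
    survival::coxph(
      f, data = d, ties = "efron", robust = TRUE,
      weights = if (is.null(w)) NULL else d$.w,
      cluster = patient_id, x = FALSE, y = TRUE, model = FALSE
    )
  } else {
    survival::coxph(
      f, data = d, ties = "efron",
      weights = if (is.null(w)) NULL else d$.w,
      x = FALSE, y = TRUE, model = FALSE
    )
  }
  new_ckd_fit(fit, d, spec = list(
    stage = "causal", estimator = estimator, reference = reference,
    weighted = !is.null(w)
  ))
}

#' Patient-clustered sandwich variance for a Cox fit
#'
#' Aggregates dfbeta residuals (score contributions premultiplied by the
#' inverse information) within clusters and returns the sandwich covariance
#' `t(D) %*% D`, the standard robust variance for weighted (IPTW) partial
#' likelihood estimation.
#'
#' @param fit a `coxph` fit or a `ckd_fit`.
#' @param cluster cluster identifiers, one per observation used in the fit
#'   (defaults to the `cluster` term supplied at fit time, if any).
#' @return List with `vcov` (robust covariance matrix) and `se` (robust SEs).
#' @export
robust_variance <- function(fit, cluster = NULL) {
  if (inherits(fit, "ckd_fit")) fit <- fit$fit
  db <- stats::residuals(fit, type = "dfbeta",
                         collapse = if (is.null(cluster)) NULL else cluster)
  db <- as.matrix(db)
  V <- crossprod(db)
  if (any(!is.finite(V))) stop("singular information matrix", call. = FALSE)
  dimnames(V) <- list(names(coef(fit)), names(coef(fit)))
  list(vcov = V, se = sqrt(diag(V)))
}

#' Run the full pipeline on replicated simulated cohorts
#'
#' For each replicate: simulate a cohort under `config` (with seed
#' `config$seed + rep`), run data preparation, estimate stabilized weights,
#' and fit the requested estimators. Used by [compare_estimators()] and the
#' package's calibration studies.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates.
#' @param estimators subset of `c("crude", "adjusted", "weighted",
#'   "doubly_robust")`.
#' @param terms regimen contrasts to keep (default `TDF_rbPI`).
#' @return Tibble with one row per replicate x estimator x contrast:
#'   `log_hr`, `robust_se`, `conf_low`/`conf_high` (log scale), `n_events`,
#'   plus a `failed` flag for replicates whose fit errored.
#' @export
run_estimator_replicates <- function(config, n_reps = 20,
                                     estimators = c("crude", "weighted"),
                                     terms = "TDF_rbPI") {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    class(cfg) <- "sim_config"
    res <- tryCatch({
      sim <- simulate_cohort(cfg)
      prep <- prepare_cohort(sim$patients, sim$labs, sim$regimens)
      pm <- prep$person_months
      wts <- if (any(c("weighted", "doubly_robust") %in% estimators)) {
        suppressWarnings(suppressMessages(estimate_weights(pm)$weights))
      } else NULL
      purrr::map_dfr(estimators, function(est) {
        f <- suppressWarnings(
          fit_msm(pm, weights = wts, estimator = est,
                  robust = est != "crude"))
        tidy(f) %>%
          filter(.data$exposure,
                 sub("^exposure_initial", "", .data$term) %in% terms) %>%
          transmute(
            rep = r, estimator = est,
            term = sub("^exposure_initial", "", .data$term),
            log_hr = log(.data$hr),
            robust_se = .data$robust_se,
            conf_low = log(.data$hr) - 1.96 * .data$robust_se,
            conf_high = log(.data$hr) + 1.96 * .data$robust_se,
            n_events = f$n_events, failed = FALSE
          )
      })
    }, error = function(e) {
      tibble(rep = r, estimator = estimators, term = NA_character_,
             log_hr = NA_real_, robust_se = NA_real_, conf_low = NA_real_,
             conf_high = NA_real_, n_events = NA_integer_, failed = TRUE)
    })
    res
  })
}

#' Compare estimators against the counterfactual oracle
#'
#' Monte-Carlo bias, RMSE, empirical and mean robust SE, and 95% CI coverage
#' per estimator and contrast, with the oracle marginal log HR as the truth.
#'
#' @param replicates tibble from [run_estimator_replicates()] (all replicates
#'   must come from one configuration).
#' @param oracle tibble from [simulate_counterfactual_reference()].
#' @return Tibble, one row per estimator x contrast.
#' @export
compare_estimators <- function(replicates, oracle) {
  ok <- replicates %>% filter(!.data$failed)
  if (nrow(ok) < 2) stop("need at least 2 successful replicates", call. = FALSE)
  ok %>%
    left_join(oracle %>% select("term", truth = "log_hr"), by = "term") %>%
    group_by(.data$estimator, .data$term) %>%
    summarise(
      n_reps = dplyr::n(),
      truth = dplyr::first(.data$truth),
      mean_log_hr = mean(.data$log_hr),
      median_log_hr = median(.data$log_hr),
      bias = mean(.data$log_hr) - dplyr::first(.data$truth),
      median_bias = median(.data$log_hr) - dplyr::first(.data$truth),
      rmse = sqrt(mean((.data$log_hr - dplyr::first(.data$truth))^2)),
      empirical_se = sd(.data$log_hr),
      mean_robust_se = mean(.data$robust_se),
      coverage = mean(.data$conf_low <= dplyr::first(.data$truth) &
                        .data$conf_high >= dplyr::first(.data$truth)),
      .groups = "drop"
    )
}
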