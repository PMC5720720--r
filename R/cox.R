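baseline_covariates <- function() {
  c("age_at_start", "nadir_cd4", "baseline_cd4", "baseline_vl_log10",
    "baseline_egfr", "year_of_start", "sex", "hiv_exposure",
    "hbv", "hcv", "diabetes", "hypertension", "cvd")
}

tv_covariates <- function() c("cd4_cat", "vl_cat")

# wrap a fitted coxph into the common result container
new_ckd_fit <- function(fit, data, spec) {
  beta <- coef(fit)
  keep <- grep("^exposure_", names(beta), value = TRUE)
  se_model <- sqrt(diag(if (is.null(fit$naive.var)) fit$var else fit$naive.var))
  se_robust <- sqrt(diag(fit$var))
  names(se_model) <- names(se_robust) <- names(beta)
  terms_tbl <- tibble(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se_model),
    robust_se = unname(se_robust),
    hr = exp(unname(beta)),
    conf_low = exp(unname(beta) - 1.96 * unname(se_robust)),
    conf_high = exp(unname(beta) + 1.96 * unname(se_robust)),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se_robust))),
    exposure = .data$term %in% keep,
    suppressed = grepl("OTHER", .data$term),
    infinite_se = !is.finite(beta) | unname(se_robust) > 50 | abs(beta) > 15
  )
  structure(
    list(
      fit = fit,
      terms = terms_tbl,
      spec = spec,
      n_events = sum(data$event),
      n_person_months = nrow(data),
      n_patients = dplyr::n_distinct(data$patient_id),
      converged = is.null(fit$fail),
      iter = fit$iter
    ),
    class = "ckd_fit"
  )
}

#' Traditional proportional hazards models for all CKD events
#'
#' The first analysis series: Cox models on person-month counting-process
#' data (each month contributes the interval `(m-1, m]`) with Efron tie
#' handling, under three exposure codings — the initial regimen type
#' (`"initial"`), the current type as a time-varying covariate (`"current"`),
#' or current plus the immediately preceding type
#' (`"current_plus_previous"`). Adjusted models include the baseline
#' confounder set and time-varying CD4 and viral-load categories
#' (last-value-carried-forward). `OTHER` regimen terms are estimated but
#' flagged as suppressed in reports.
#'
#' @param person_months person-month tibble from [expand_person_months()].
#' @param exposure_coding one of `"initial"`, `"current"`,
#'   `"current_plus_previous"`.
#' @param censor_at_switch restrict follow-up to the initial regimen
#'   (incompatible with `"current_plus_previous"`).
#' @param adjusted include baseline and time-varying covariates.
#' @param reference reference regimen type (default `"TDF_NNRTI"`).
#' @param continuous_form `"linear"` (default) or `"rcs"` (3-knot restricted
#'   cubic splines) for continuous baseline confounders.
#' @param weights optional numeric person-month weights (e.g. stabilized
#'   IPTW), aligned with the rows of `person_months`.
#' @return A `ckd_fit`; see [tidy.ckd_fit()] and [glance.ckd_fit()].
#' @export
fit_cox <- function(person_months,
                    exposure_coding = c("initial", "current",
                                        "current_plus_previous"),
                    censor_at_switch = FALSE,
                    adjusted = TRUE,
                    reference = "TDF_NNRTI",
                    continuous_form = c("linear", "rcs"),
                    weights = NULL) {
  exposure_coding <- match.arg(exposure_coding)
  continuous_form <- match.arg(continuous_form)
  if (exposure_coding == "current_plus_previous" && censor_at_switch) {
    stop("`current_plus_previous` requires `censor_at_switch = FALSE`",
         call. = FALSE)
  }
  d <- person_months
  if (!is.null(weights)) d$.w <- weights
  if (censor_at_switch) d <- d %>% filter(.data$on_initial)

  d$exposure_initial <- stats::relevel(regimen_factor(d$initial_regimen),
                                       ref = reference)
  d$exposure_current <- stats::relevel(regimen_factor(d$current_regimen),
                                       ref = reference)
  prev <- as.character(d$previous_regimen)
  prev[is.na(prev)] <- "none"
  d$exposure_previous <- factor(prev, levels = c("none", regimen_levels()))

  rhs <- switch(exposure_coding,
                initial = "exposure_initial",
                current = "exposure_current",
                current_plus_previous = c("exposure_current", "exposure_previous"))
  if (adjusted) {
    cont <- c("age_at_start", "nadir_cd4", "baseline_cd4",
              "baseline_vl_log10", "baseline_egfr")
    if (continuous_form == "rcs") {
      for (v in cont) {
        b <- rcs_basis(d[[v]])
        d[[paste0(v, "_rcs")]] <- b[, "nonlin"]
      }
      cont <- c(cont, paste0(cont, "_rcs"))
    }
    rhs <- c(rhs, cont, setdiff(baseline_covariates(),
                                c("age_at_start", "nadir_cd4", "baseline_cd4",
                                  "baseline_vl_log10", "baseline_egfr")),
             tv_covariates())
  }
  f <- reformulate(rhs, response = "survival::Surv(tstart, tstop, event)")
  fit <- survival::coxph(
    f, data = d, ties = "efron", robust = TRUE,
    weights = if (is.null(weights)) NULL else d$.w,
    cluster = patient_id, x = FALSE, y = TRUE, model = FALSE
  )
  new_ckd_fit(fit, d, spec = list(
    stage = "traditional", exposure_coding = exposure_coding,
    censor_at_switch = censor_at_switch, adjusted = adjusted,
    reference = reference, continuous_form = continuous_form,
    weighted = !is.null(weights)
  ))
}

#' Incidence of confirmed CKD per 1000 person-years
#'
#' Events divided by person-time (person-months x 30.44 / 365.25), with
#' exact Poisson confidence limits; computed overall and restricted to
#' follow-up on the initial regimen type.
#'
#' @param person_months person-month tibble.
#' @return Tibble with rows `overall` and `on_initial`: events, person-years,
#'   rate per 1000 person-years and exact 95% CI.
#' @export
summarize_incidence <- function(person_months) {
  one <- function(d, scope) {
    py <- nrow(d) * MONTH_DAYS / 365.25
    if (py <= 0) stop("zero person-time", call. = FALSE)
    ev <- sum(d$event)
    ci <- stats::poisson.test(ev, py)$conf.int
    tibble(scope = scope, events = ev, person_years = py,
           rate_per_1000py = 1000 * ev / py,
           conf_low = 1000 * ci[1], conf_high = 1000 * ci[2])
  }
  bind_rows(
    one(person_months, "overall"),
    one(person_months %>% filter(.data$on_initial), "on_initial")
  )
}
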