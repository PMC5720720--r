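#' Baseline treatment model and its stabilized weight component
#'
#' Fits a polytomous (multinomial) logistic model of the initial regimen type
#' on the baseline confounders, with continuous covariates entered as linear
#' terms. The stabilized baseline weight is the marginal frequency of the
#' patient's observed type (numerator) over the model probability of that
#' type given covariates (denominator). Fitted probabilities are floored at
#' `prob_floor` (with a warning) to guard against separation.
#'
#' @param patients one row per patient, including `initial_regimen` and the
#'   baseline confounders.
#' @param formula optional model formula overriding the default covariate
#'   set.
#' @param prob_floor lower bound on the denominator probability.
#' @return List with `sw_a` (tibble `patient_id`, `numerator`, `denominator`,
#'   `sw_a`) and `model` (the `multinom` fit).
#' @export
fit_baseline_treatment_model <- function(patients, formula = NULL,
                                         prob_floor = 1e-6) {
  d <- patients
  d$initial_regimen <- droplevels(regimen_factor(d$initial_regimen))
  if (!"year_of_start" %in% names(d) && "art_start_date" %in% names(d)) {
    d$year_of_start <- as.integer(format(d$art_start_date, "%Y"))
  }
  if (is.null(formula)) {
    formula <- reformulate(baseline_covariates(), response = "initial_regimen")
  }
  if (nlevels(d$initial_regimen) == 2) {
    # the polytomous model reduces to one logistic fit; IRLS converges to
    # machine-level probabilities
    lv <- levels(d$initial_regimen)
    f2 <- stats::update(formula, .bin ~ .)
    d$.bin <- as.integer(d$initial_regimen == lv[2])
    fit <- glm(f2, data = d, family = binomial(),
               control = stats::glm.control(epsilon = 1e-12))
    p2 <- predict(fit, type = "response")
    pr <- cbind(1 - p2, p2)
    colnames(pr) <- lv
  } else {
    fit <- nnet::multinom(formula, data = d, trace = FALSE, maxit = 500,
                          reltol = 1e-10)
    pr <- predict(fit, newdata = d, type = "probs")
  }
  obs <- as.character(d$initial_regimen)
  den <- pr[cbind(seq_len(nrow(d)), match(obs, colnames(pr)))]
  if (any(den < prob_floor)) {
    warning(sum(den < prob_floor),
            " fitted treatment probabilit(ies) below the floor of ",
            prob_floor, " (possible separation); floored", call. = FALSE)
    den <- pmax(den, prob_floor)
  }
  num <- as.numeric(table(d$initial_regimen)[obs] / nrow(d))
  list(
    sw_a = tibble(patient_id = d$patient_id, numerator = num,
                  denominator = den, sw_a = num / den),
    model = fit
  )
}

# add spline-basis columns for the weight models; knots computed from the
# realized distribution of each spanned variable
add_weight_bases <- function(d, spline_vars, knots = NULL) {
  if (is.null(knots)) {
    knots <- lapply(spline_vars, function(v) rcs_knots(d[[v]]))
    names(knots) <- spline_vars
  }
  for (v in spline_vars) {
    b <- rcs_basis(d[[v]], knots[[v]])
    d[[paste0(v, "_rcs")]] <- b[, "nonlin"]
  }
  attr(d, "weight_knots") <- knots
  d
}

weight_spline_vars <- function() {
  c("month", "age_at_start", "nadir_cd4", "baseline_cd4",
    "baseline_vl_log10", "baseline_egfr")
}

weight_model_formulas <- function(tv = TRUE, pooled = FALSE,
                                  time_only = FALSE) {
  if (time_only) {
    rhs <- c("month", "month_rcs")
  } else {
    sv <- weight_spline_vars()
    rhs <- c(sv, paste0(sv, "_rcs"), "year_of_start", "sex", "hiv_exposure",
             "hbv", "hcv", "diabetes", "hypertension", "cvd")
    if (tv) rhs <- c(rhs, "cd4_cat", "vl_cat", "egfr_cat")
  }
  if (pooled) rhs <- c(rhs, "initial_regimen")
  rhs
}

#' Pooled logistic models for switching and censoring weights
#'
#' Fits, separately within each initial-regimen stratum (with a pooled
#' fallback when a stratum has fewer than `min_events` switch events), four
#' pooled logistic regressions on the on-initial person-months: the switch
#' denominator (restricted-cubic-spline time intercept, 3-knot splines of the
#' continuous baseline covariates, year linear, and step-function
#' time-varying CD4 / viral load / eGFR categories), the switch numerator
#' (same minus the time-varying terms), and the analogous censoring pair.
#' Returns the per-row probabilities of *remaining* unswitched and uncensored
#' under each model.
#'
#' @param person_months on-initial person-month rows (rows with
#'   `on_initial = FALSE` are dropped).
#' @param stratify `"tdf"` (default): separate fits for tenofovir-containing
#'   versus tenofovir-free initial regimens, with initial-regimen main
#'   effects inside each stratum (switching behaviour differs mainly by TDF
#'   exposure, and two strata keep the per-model event counts high enough
#'   that estimation noise does not accumulate in the cumulative weight
#'   products); `"regimen"`: one fit per initial regimen type; `"none"`:
#'   pooled fits with regimen main effects.
#' @param min_events minimum switch events for a stratum-specific fit.
#' @param prob_floor lower bound applied to remain-probabilities.
#' @param numerator `"baseline"` (default): the stabilizing numerator models
#'   carry the spline time intercept plus the baseline-covariate terms (the
#'   switch/censor denominators minus the time-varying step functions),
#'   which keeps the weight distribution narrow; `"time"`: the numerators
#'   carry only the time intercept, the strictly marginal-safe choice when
#'   the weighted outcome model is covariate-free and switching or censoring
#'   depends strongly on baseline covariates. With weak baseline dependence
#'   of switching the two agree; see the methods vignette.
#' @param formula_den,formula_num optional formula overrides (applied to both
#'   the switch and censor models; mainly for testing).
#' @param glm_epsilon IRLS convergence tolerance for the pooled logistic
#'   fits.
#' @return List with `probabilities` (tibble `patient_id`, `month`,
#'   `num_switch`, `den_switch`, `num_cens`, `den_cens`), `models`, `knots`
#'   and `fallback_strata`.
#' @export
fit_switch_and_censor_models <- function(person_months,
                                         stratify = c("tdf", "regimen", "none"),
                                         min_events = 5, prob_floor = 1e-6,
                                         numerator = c("baseline", "time"),
                                         formula_den = NULL,
                                         formula_num = NULL,
                                         glm_epsilon = 1e-7) {
  if (is.logical(stratify)) stratify <- if (stratify) "regimen" else "none"
  stratify <- match.arg(stratify)
  numerator <- match.arg(numerator)
  num_time_only <- numerator == "time"
  d <- person_months %>% filter(.data$on_initial)
  d$initial_regimen <- regimen_factor(d$initial_regimen)
  d <- add_weight_bases(d, setdiff(weight_spline_vars(), "month"))
  knots <- attr(d, "weight_knots")
  b <- rcs_basis(d$month, rcs_knots(d$month))
  d$month_rcs <- b[, "nonlin"]
  knots$month <- rcs_knots(d$month)

  build_X <- function(rhs, pooled = FALSE) {
    if (inherits(rhs, "formula")) {
      model.matrix(rhs, d)
    } else {
      model.matrix(reformulate(if (pooled) c(rhs, "initial_regimen") else rhs), d)
    }
  }
  f_den <- if (is.null(formula_den)) weight_model_formulas(tv = TRUE) else formula_den
  f_num <- if (is.null(formula_num)) {
    weight_model_formulas(tv = FALSE, time_only = num_time_only)
  } else formula_num
  X_den <- build_X(f_den)
  X_num <- build_X(f_num)
  X_den_p <- if (is.null(formula_den)) {
    build_X(weight_model_formulas(tv = TRUE), pooled = TRUE)
  } else X_den
  X_num_p <- if (is.null(formula_num)) {
    build_X(weight_model_formulas(tv = FALSE, time_only = num_time_only),
            pooled = TRUE)
  } else X_num
  y_sw <- as.numeric(d$switched_this_month)
  y_cs <- as.numeric(d$censored_this_month)

  # fit on the design rows directly; remain-probability = 1 - fitted hazard.
  # IRLS warm-starts at the intercept-only solution (saves ~2 iterations on
  # rare-event outcomes; identical fit)
  fit_rows <- function(X, y, fit_rows_idx, pred_rows_idx) {
    Xg <- X[fit_rows_idx, , drop = FALSE]
    keep <- c(TRUE, col_vars(Xg[, -1, drop = FALSE]) > 0)
    p0 <- min(max(mean(y[fit_rows_idx]), 1e-6), 1 - 1e-6)
    fit <- suppressWarnings(stats::glm.fit(Xg[, keep, drop = FALSE],
                                           y[fit_rows_idx],
                                           family = binomial(),
                                           start = c(qlogis(p0),
                                                     rep(0, sum(keep) - 1L)),
                                           control = stats::glm.control(epsilon = glm_epsilon)))
    p <- fit$fitted.values
    if (!identical(fit_rows_idx, pred_rows_idx)) {
      p <- p[match(pred_rows_idx, fit_rows_idx)]
    }
    list(prob = pmin(pmax(1 - p, prob_floor), 1),
         coef = setNames(fit$coefficients, colnames(Xg)[keep]),
         converged = fit$converged)
  }

  models <- list()
  fallback <- character(0)
  probs <- d %>% select("patient_id", "month")
  probs$num_switch <- probs$den_switch <- NA_real_
  probs$num_cens <- probs$den_cens <- NA_real_
  all_rows <- seq_len(nrow(d))
  strata_def <- switch(
    stratify,
    regimen = split(all_rows, d$initial_regimen),
    tdf = split(all_rows,
                ifelse(d$initial_regimen %in% c("TDF_NNRTI", "TDF_rbPI"),
                       "TDF", "noTDF")),
    none = NULL
  )

  assign_probs <- function(rows, fit_rows_idx, pooled) {
    Xd <- if (pooled) X_den_p else X_den
    Xn <- if (pooled) X_num_p else X_num
    sd_ <- fit_rows(Xd, y_sw, fit_rows_idx, rows)
    sn_ <- fit_rows(Xn, y_sw, fit_rows_idx, rows)
    cd_ <- fit_rows(Xd, y_cs, fit_rows_idx, rows)
    cn_ <- fit_rows(Xn, y_cs, fit_rows_idx, rows)
    probs$den_switch[rows] <<- sd_$prob
    probs$num_switch[rows] <<- sn_$prob
    probs$den_cens[rows] <<- cd_$prob
    probs$num_cens[rows] <<- cn_$prob
    list(switch_den = sd_$coef, switch_num = sn_$coef,
         cens_den = cd_$coef, cens_num = cn_$coef)
  }

  if (is.null(strata_def)) {
    models$pooled <- assign_probs(all_rows, all_rows, pooled = TRUE)
  } else {
    for (g in names(strata_def)) {
      rows <- strata_def[[g]]
      if (length(rows) == 0) next
      if (sum(y_sw[rows]) < min_events) {
        fallback <- c(fallback, g)
        models$pooled <- assign_probs(rows, all_rows, pooled = TRUE)
      } else {
        models[[g]] <- assign_probs(rows, rows, pooled = TRUE)
      }
    }
    if (length(fallback) > 0) {
      message("pooled weight-model fallback for sparse strata: ",
              paste(fallback, collapse = ", "))
    }
  }

  list(probabilities = probs, models = models, knots = knots,
       fallback_strata = fallback)
}

# column variances without matrixStats (small helper; exact zeros matter,
# not numerical efficiency of the variance itself)
col_vars <- function(X) {
  if (ncol(X) == 0) return(numeric(0))
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

#' Cumulative stabilized weights SW(t)
#'
#' Combines the baseline treatment component with the monthly switch and
#' censoring probability ratios:
#' `SW(t) = sw_a x prod_{k<=t} (num_switch_k x num_cens_k) /
#' (den_switch_k x den_cens_k)`, computed per patient along the on-initial
#' months. Optional symmetric percentile truncation is off by default.
#'
#' @param sw_a tibble from [fit_baseline_treatment_model()] (`$sw_a`), or a
#'   tibble with `patient_id` and `sw_a`.
#' @param monthly_probs tibble from [fit_switch_and_censor_models()]
#'   (`$probabilities`).
#' @param truncate_quantiles `NULL` (no truncation) or a length-2 probability
#'   pair such as `c(0.01, 0.99)`.
#' @return WeightSet tibble: `patient_id`, `month`, `sw_a`, the four monthly
#'   probabilities, and `sw_t`.
#' @export
compute_stabilized_weights <- function(sw_a, monthly_probs,
                                       truncate_quantiles = NULL) {
  if (!is.data.frame(sw_a)) stop("`sw_a` must be a tibble", call. = FALSE)
  p <- monthly_probs
  bad <- p$den_switch <= 0 | p$den_cens <= 0 | !is.finite(p$den_switch) |
    !is.finite(p$den_cens)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("zero/invalid denominator probability for patient ",
         p$patient_id[i], ", month ", p$month[i], call. = FALSE)
  }
  w <- p %>%
    left_join(sw_a %>% select("patient_id", "sw_a"), by = "patient_id") %>%
    arrange(.data$patient_id, .data$month) %>%
    group_by(.data$patient_id) %>%
    mutate(sw_t = .data$sw_a * cumprod((.data$num_switch * .data$num_cens) /
                                         (.data$den_switch * .data$den_cens))) %>%
    ungroup() %>%
    select("patient_id", "month", "sw_a", "num_switch", "den_switch",
           "num_cens", "den_cens", "sw_t")
  if (!is.null(truncate_quantiles)) {
    q <- quantile(w$sw_t, truncate_quantiles)
    w$sw_t <- pmin(pmax(w$sw_t, q[1]), q[2])
  }
  w
}

#' One-call stabilized weight estimation
#'
#' Runs the baseline treatment model, the stratified switch/censor pooled
#' logistic models, and the cumulative product on a person-month table.
#'
#' @inheritParams fit_switch_and_censor_models
#' @inheritParams compute_stabilized_weights
#' @return List with `weights` (WeightSet), `treatment_model`,
#'   `switch_censor`, and `diagnostics`.
#' @export
estimate_weights <- function(person_months, stratify = c("tdf", "regimen", "none"),
                             truncate_quantiles = NULL, min_events = 5,
                             numerator = c("baseline", "time")) {
  pts <- person_months %>%
    filter(.data$on_initial) %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    select("patient_id", "initial_regimen",
           dplyr::all_of(baseline_covariates()))
  trt <- fit_baseline_treatment_model(pts)
  sc <- fit_switch_and_censor_models(person_months, stratify = stratify,
                                     min_events = min_events,
                                     numerator = numerator)
  w <- compute_stabilized_weights(trt$sw_a, sc$probabilities,
                                  truncate_quantiles = truncate_quantiles)
  list(weights = w, treatment_model = trt, switch_censor = sc,
       diagnostics = weight_diagnostics(w))
}

#' Stabilized weight diagnostics
#'
#' Overall moments, range, the per-month weight distribution (box-plot-ready
#' quantiles) and the most extreme person-months.
#'
#' @param weights WeightSet tibble from [compute_stabilized_weights()].
#' @param n_extreme how many extreme rows to list.
#' @return List of class `weight_diagnostics` with `summary`, `by_month`,
#'   `extremes`.
#' @export
weight_diagnostics <- function(weights, n_extreme = 10) {
  summary <- tibble(
    n = nrow(weights),
    mean = mean(weights$sw_t),
    sd = sd(weights$sw_t),
    min = min(weights$sw_t),
    max = max(weights$sw_t)
  )
  by_month <- weights %>%
    group_by(.data$month) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$sw_t),
      q05 = quantile(.data$sw_t, 0.05),
      q25 = quantile(.data$sw_t, 0.25),
      q50 = quantile(.data$sw_t, 0.50),
      q75 = quantile(.data$sw_t, 0.75),
      q95 = quantile(.data$sw_t, 0.95),
      .groups = "drop"
    )
  extremes <- weights %>%
    arrange(dplyr::desc(abs(log(.data$sw_t)))) %>%
    head(n_extreme)
  structure(list(summary = summary, by_month = by_month, extremes = extremes),
            class = "weight_diagnostics")
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Stabilized weights: n = %d, mean = %.3f (SD %.3f), range %.3f-%.3f\n",
    s$n, s$mean, s$sd, s$min, s$max))
  invisible(x)
}
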