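#' Aggregate person-months into switch-count cells
#'
#' Each person-month contributes one month of exposure to its (regimen type,
#' current eGFR category) cell; a switch event is assigned to the cell active
#' in its month. In `"any_regimen"` mode every regimen spell contributes
#' (switch flags exist for every category change); `"initial_only"` restricts
#' to follow-up on the initial type.
#'
#' @param person_months person-month tibble.
#' @param mode `"any_regimen"` or `"initial_only"`.
#' @param adjusters optional names of baseline columns to carry into the
#'   cells (continuous adjusters are aggregated by their cell mean).
#' @return Tibble with `regimen`, `egfr_cat`, any adjusters, `switch_count`
#'   and `person_time` (months).
#' @export
build_switch_counts <- function(person_months,
                                mode = c("any_regimen", "initial_only"),
                                adjusters = NULL) {
  mode <- match.arg(mode)
  d <- person_months
  if (mode == "initial_only") d <- d %>% filter(.data$on_initial)
  grp <- c("current_regimen", "egfr_cat", adjusters)
  d %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(
      switch_count = sum(.data$switched_this_month),
      person_time = dplyr::n(),
      .groups = "drop"
    ) %>%
    rename(regimen = "current_regimen")
}

#' Negative-binomial incidence rate ratios of regimen discontinuation
#'
#' Fits, per regimen type, an NB2 negative-binomial regression (variance
#' `mu + alpha mu^2`, dispersion by maximum likelihood) of switch counts on
#' the current eGFR category with a log person-time offset, optionally with
#' baseline adjusters as linear terms. The reference category is eGFR > 90.
#' When the dispersion estimate does not converge the fit falls back to
#' Poisson with overdispersion-scaled standard errors (and says so).
#'
#' @param records cell tibble from [build_switch_counts()].
#' @param adjusters optional adjuster column names present in `records`.
#' @param regimens regimen types to fit (default: all present with at least
#'   two eGFR categories of nonzero person-time).
#' @return Tibble, one row per regimen x non-reference eGFR category: `irr`,
#'   `conf_low`, `conf_high`, `p_value`, `dispersion`, `family`.
#' @export
fit_negbin_irr <- function(records, adjusters = NULL, regimens = NULL) {
  records <- records %>% filter(.data$person_time > 0)
  if (is.null(regimens)) {
    regimens <- records %>%
      count(.data$regimen, .data$egfr_cat) %>%
      count(.data$regimen) %>%
      filter(.data$n >= 2) %>%
      pull(.data$regimen) %>%
      as.character()
  }
  rhs <- c("egfr_cat", adjusters)
  f <- reformulate(c(rhs, "offset(log(person_time))"),
                   response = "switch_count")
  purrr::map_dfr(regimens, function(g) {
    dg <- records %>% filter(.data$regimen == g) %>%
      mutate(egfr_cat = droplevels(.data$egfr_cat))
    fam <- "negbin"
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(f, data = dg, maxit = 100)),
      error = function(e) NULL
    )
    theta <- if (!is.null(fit)) fit$theta else NA_real_
    if (is.null(fit) || !fit$converged) {
      fam <- "poisson_quasilikelihood"
      fit <- glm(f, data = dg, family = poisson())
      phi <- max(1, sum(stats::residuals(fit, "pearson")^2) / fit$df.residual)
      V <- vcov(fit) * phi
      message("negative-binomial dispersion did not converge for ", g,
              "; Poisson with overdispersion-scaled SEs used")
    } else {
      V <- vcov(fit)
    }
    beta <- coef(fit)
    keep <- grep("^egfr_cat", names(beta))
    se <- sqrt(diag(V))[keep]
    tibble(
      regimen = g,
      egfr_cat = sub("^egfr_cat", "", names(beta)[keep]),
      log_irr = unname(beta[keep]),
      irr = exp(unname(beta[keep])),
      conf_low = exp(unname(beta[keep]) - 1.96 * se),
      conf_high = exp(unname(beta[keep]) + 1.96 * se),
      p_value = 2 * pnorm(-abs(unname(beta[keep]) / se)),
      dispersion = if (fam == "negbin") 1 / theta else NA_real_,
      family = fam
    )
  })
}
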