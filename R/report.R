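#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> prepare -> traditional Cox fits ->
#' stabilized weights -> causal fits -> discontinuation models -> summaries,
#' returning a machine-readable report bundle. Any subset of stages can be
#' toggled; later stages reuse whatever earlier artifacts they need.
#'
#' @param config a [sim_config()] (used when `cohort` is `NULL`).
#' @param cohort optional list with `patients`, `labs`, `regimens` (e.g. from
#'   [read_cohort()]); when supplied, no simulation is run.
#' @param stages character subset of
#'   `c("traditional", "causal", "discontinuation")`.
#' @param out_dir optional directory: writes `person_months.csv`,
#'   `weights.csv`, `exclusions.csv` and `results.json`.
#' @param truncate_quantiles passed to [estimate_weights()].
#' @return List of class `ckd_report`: `incidence`, `baseline_table`,
#'   `traditional` (tidy tibble per exposure coding), `causal` (tidy tibble
#'   per estimator), `weight_diagnostics`, `discontinuation`, `exclusions`,
#'   and `meta`.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL,
                         stages = c("traditional", "causal",
                                    "discontinuation"),
                         out_dir = NULL, truncate_quantiles = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(cohort)) {
    if (is.null(config)) stop("supply `config` or `cohort`", call. = FALSE)
    cohort <- simulate_cohort(config)
  }
  prep <- prepare_cohort(cohort$patients, cohort$labs, cohort$regimens)
  pm <- prep$person_months
  report <- list(
    incidence = summarize_incidence(pm),
    baseline_table = make_baseline_table(prep$patients),
    exclusions = prep$exclusions,
    meta = list(
      n_eligible = nrow(prep$patients),
      n_events = sum(pm$event),
      n_person_months = nrow(pm),
      seed = if (!is.null(config)) config$seed else NA,
      stages = stages,
      timestamp = NA  # no wall-clock state in the report (determinism)
    )
  )

  if ("traditional" %in% stages) {
    report$traditional <- purrr::map_dfr(
      c("initial", "current", "current_plus_previous"),
      function(coding) {
        tidy(fit_cox(pm, exposure_coding = coding)) %>%
          filter(.data$exposure) %>%
          mutate(model = coding, .before = 1)
      })
  }
  if ("causal" %in% stages) {
    wts <- estimate_weights(pm, truncate_quantiles = truncate_quantiles)
    report$weight_diagnostics <- wts$diagnostics
    report$causal <- purrr::map_dfr(
      c("crude", "adjusted", "weighted", "doubly_robust"),
      function(est) {
        tidy(fit_msm(pm, weights = wts$weights, estimator = est)) %>%
          filter(.data$exposure) %>%
          mutate(estimator = est, .before = 1)
      })
    report$weights <- wts$weights
  }
  if ("discontinuation" %in% stages) {
    report$discontinuation <- bind_rows(
      build_switch_counts(pm, "any_regimen") %>%
        fit_negbin_irr() %>% mutate(mode = "any_regimen", .before = 1),
      build_switch_counts(pm, "initial_only") %>%
        fit_negbin_irr() %>% mutate(mode = "initial_only", .before = 1)
    )
  }

  class(report) <- "ckd_report"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(pm, file.path(out_dir, "person_months.csv"))
    readr::write_csv(prep$exclusions, file.path(out_dir, "exclusions.csv"))
    if (!is.null(report$weights)) {
      readr::write_csv(report$weights, file.path(out_dir, "weights.csv"))
    }
    json <- report[setdiff(names(report),
                           c("weights", "weight_diagnostics"))]
    json$weight_summary <- if (!is.null(report$weight_diagnostics)) {
      report$weight_diagnostics$summary
    }
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.ckd_report <- function(x, ...) {
  cat("ckdmsm pipeline report\n")
  cat(sprintf("  eligible patients: %d, events: %d, person-months: %d\n",
              x$meta$n_eligible, x$meta$n_events, x$meta$n_person_months))
  inc <- x$incidence
  cat(sprintf("  CKD incidence: %.1f /1000 PY overall (95%% CI %.1f-%.1f), %.1f on initial regimen\n",
              inc$rate_per_1000py[1], inc$conf_low[1], inc$conf_high[1],
              inc$rate_per_1000py[2]))
  if (!is.null(x$weight_diagnostics)) print(x$weight_diagnostics)
  if (!is.null(x$causal)) {
    main <- x$causal %>%
      filter(.data$term == "exposure_initialTDF_rbPI", !.data$suppressed)
    for (i in seq_len(nrow(main))) {
      cat(sprintf("  %-13s TDF+/rbPI vs TDF+/NNRTI: HR %.2f (%.2f-%.2f)\n",
                  main$estimator[i], main$hr[i], main$conf_low[i],
                  main$conf_high[i]))
    }
  }
  invisible(x)
}

#' Descriptive baseline table
#'
#' Median (IQR) for continuous covariates and n (%) for categorical ones,
#' overall and by initial regimen type.
#'
#' @param patients eligible patient tibble with `initial_regimen`.
#' @return Tibble: `variable`, `statistic`, one column per group (`All` plus
#'   each regimen type present).
#' @export
make_baseline_table <- function(patients) {
  pts <- patients %>% mutate(initial_regimen = regimen_factor(.data$initial_regimen))
  groups <- c("All", levels(droplevels(pts$initial_regimen)))
  cont <- c(age = "age_at_start", egfr = "baseline_egfr",
            cd4 = "baseline_cd4", vl_log10 = "baseline_vl_log10",
            nadir_cd4 = "nadir_cd4")
  cont <- cont[unname(cont) %in% names(pts)]
  cats <- list(
    male = function(d) d$sex == "male",
    homosexual_exposure = function(d) d$hiv_exposure == "homosexual",
    heterosexual_exposure = function(d) d$hiv_exposure == "heterosexual",
    hbv = function(d) d$hbv, hcv = function(d) d$hcv,
    hypertension = function(d) d$hypertension, cvd = function(d) d$cvd,
    diabetes = function(d) d$diabetes
  )
  cell_cont <- function(d, v) {
    q <- quantile(d[[v]], c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.0f (%.0f-%.0f)", q[2], q[1], q[3])
  }
  cell_cat <- function(d, f) {
    x <- f(d)
    sprintf("%d (%.0f)", sum(x, na.rm = TRUE), 100 * mean(x, na.rm = TRUE))
  }
  subsets <- c(list(All = pts),
               setNames(lapply(groups[-1],
                               function(g) pts %>% filter(.data$initial_regimen == g)),
                        groups[-1]))
  rows <- list(tibble(variable = "n", statistic = "count",
                      !!!lapply(subsets, function(d) as.character(nrow(d)))))
  for (nm in names(cont)) {
    rows <- c(rows, list(tibble(
      variable = nm, statistic = "median (IQR)",
      !!!lapply(subsets, cell_cont, v = cont[[nm]])
    )))
  }
  for (nm in names(cats)) {
    if (nm %in% c("male") || any(vapply(pts, is.logical, logical(1)))) {
      rows <- c(rows, list(tibble(
        variable = nm, statistic = "n (%)",
        !!!lapply(subsets, cell_cat, f = cats[[nm]])
      )))
    }
  }
  bind_rows(rows)
}
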