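#' Tidy a fitted model stage
#'
#' One row per coefficient: log-hazard `estimate`, model-based `se`,
#' patient-clustered `robust_se`, `hr` with robust 95% CI, Wald `p_value`,
#' an `exposure` flag for the regimen contrast terms, a `suppressed` flag for
#' `OTHER` contrasts (estimated but not reported), and `infinite_se` for
#' contrasts without events.
#'
#' @param x a `ckd_fit`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy ckd_fit
#' @export
tidy.ckd_fit <- function(x, ...) {
  x$terms
}

#' One-line model summary
#'
#' @param x a `ckd_fit`.
#' @param ... unused.
#' @return A one-row tibble: stage/estimator, events, person-months,
#'   patients, convergence.
#' @method glance ckd_fit
#' @export
glance.ckd_fit <- function(x, ...) {
  tibble(
    stage = x$spec$stage,
    model = x$spec$estimator %||% x$spec$exposure_coding,
    weighted = isTRUE(x$spec$weighted),
    n_events = x$n_events,
    n_person_months = x$n_person_months,
    n_patients = x$n_patients,
    converged = x$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ckd_fit <- function(x, ...) {
  cat(sprintf("ckd_fit [%s / %s]: %d events, %d person-months, %d patients\n",
              x$spec$stage,
              x$spec$estimator %||% x$spec$exposure_coding,
              x$n_events, x$n_person_months, x$n_patients))
  shown <- x$terms %>% filter(.data$exposure, !.data$suppressed)
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  %-35s HR %6.2f (%5.2f-%5.2f)  p = %.3g%s\n",
                shown$term[i], shown$hr[i], shown$conf_low[i],
                shown$conf_high[i], shown$p_value[i],
                if (shown$infinite_se[i]) "  [no events: SE unreliable]" else ""))
  }
  invisible(x)
}
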