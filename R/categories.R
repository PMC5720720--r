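#' Regimen and laboratory category definitions
#'
#' Antiretroviral regimens are analysed in five mutually exclusive types:
#' tenofovir (TDF) with a ritonavir-boosted protease inhibitor (`TDF_rbPI`),
#' TDF with a non-nucleoside reverse-transcriptase inhibitor (`TDF_NNRTI`),
#' the same two backbones without TDF (`noTDF_rbPI`, `noTDF_NNRTI`), and any
#' other combination (`OTHER`). `regimen_levels()` returns the levels in their
#' canonical order; `TDF_NNRTI` is the conventional reference type.
#'
#' @return Character vector of the five regimen levels.
#' @export
regimen_levels <- function() {
  c("TDF_NNRTI", "TDF_rbPI", "noTDF_NNRTI", "noTDF_rbPI", "OTHER")
}

#' @rdname regimen_levels
#' @param x character vector of regimen type names.
#' @export
regimen_factor <- function(x) {
  factor(as.character(x), levels = regimen_levels())
}

#' Categorise time-varying laboratory values
#'
#' Step-function codings used for time-varying confounders in the pooled
#' logistic weight models and the time-varying Cox adjustments: CD4 cell count
#' (<=200, 201-350, >350 cells/mm3), viral load (<=50, 51-500, >500 copies/mL)
#' and eGFR (<=50, 51-70, 71-90, >90 ml/min/1.73m2). The reference level is
#' the healthiest category in each case.
#'
#' @param x numeric vector (CD4 in cells/mm3, viral load in copies/mL, eGFR in
#'   ml/min/1.73m2).
#' @return Factor with the category levels, reference level first.
#' @export
cd4_category <- function(x) {
  cut(x, breaks = c(-Inf, 200, 350, Inf),
      labels = c("<=200", "201-350", ">350"), right = TRUE) |>
    factor(levels = c(">350", "201-350", "<=200"))
}

#' @rdname cd4_category
#' @export
vl_category <- function(x) {
  cut(x, breaks = c(-Inf, 50, 500, Inf),
      labels = c("<=50", "51-500", ">500"), right = TRUE) |>
    factor(levels = c("<=50", "51-500", ">500"))
}

#' @rdname cd4_category
#' @export
egfr_category <- function(x) {
  cut(x, breaks = c(-Inf, 50, 70, 90, Inf),
      labels = c("<=50", "51-70", "71-90", ">90"), right = TRUE) |>
    factor(levels = c(">90", "71-90", "51-70", "<=50"))
}

#' @rdname cd4_category
#' @export
egfr_levels <- function() c(">90", "71-90", "51-70", "<=50")
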