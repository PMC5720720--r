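#' Estimate GFR with the 4-variable IDMS-traceable MDRD equation
#'
#' eGFR = 175 x Scr^-1.154 x age^-0.203 x 0.742 (if female), in
#' ml/min/1.73m2. The optional race coefficient (x 1.212) is off by default
#' and available through `black`.
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param age age in years (> 0).
#' @param sex `"male"` or `"female"` (vector recycled against `scr`).
#' @param black logical; apply the 1.212 race coefficient (default `FALSE`).
#' @return eGFR in ml/min/1.73m2.
#' @examples
#' mdrd_egfr(1.0, 40, "male")
#' @export
mdrd_egfr <- function(scr, age, sex, black = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("`scr` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("`age` must be positive and finite", call. = FALSE)
  }
  sex <- match_sex(sex)
  out <- 175 * scr^(-1.154) * age^(-0.203)
  out <- out * ifelse(sex == "female", 0.742, 1)
  if (isTRUE(black)) out <- out * 1.212
  out
}

#' Invert the MDRD equation
#'
#' Serum creatinine implied by an eGFR at a given age and sex; used by the
#' synthetic cohort generator so that exported laboratory files carry
#' creatinine (the measured quantity) while the latent model works on eGFR.
#'
#' @inheritParams mdrd_egfr
#' @param egfr eGFR in ml/min/1.73m2 (> 0).
#' @return serum creatinine in mg/dL.
#' @export
scr_from_egfr <- function(egfr, age, sex, black = FALSE) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("`egfr` must be positive and finite", call. = FALSE)
  }
  sex <- match_sex(sex)
  base <- 175 * age^(-0.203) * ifelse(sex == "female", 0.742, 1)
  if (isTRUE(black)) base <- base * 1.212
  (egfr / base)^(-1 / 1.154)
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  sex
}
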