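#' Antiretroviral drug-class lookup
#'
#' Minimal drug-class dictionary used by [classify_regimen()]. Codes are the
#' usual three-letter abbreviations; a few full names are accepted as synonyms.
#'
#' @return Named character vector mapping drug code to class
#'   (`"nrti"`, `"nnrti"`, `"pi"`, `"booster"`, `"insti"`, `"other"`).
#' @export
arv_drug_classes <- function() {
  c(
    # NRTI backbone agents (TDF handled specially by classify_regimen)
    TDF = "nrti", TAF = "nrti", FTC = "nrti", `3TC` = "nrti", ABC = "nrti",
    AZT = "nrti", ZDV = "nrti", DDI = "nrti", D4T = "nrti",
    # NNRTIs
    EFV = "nnrti", NVP = "nnrti", ETR = "nnrti", RPV = "nnrti",
    EFAVIRENZ = "nnrti", NEVIRAPINE = "nnrti", ETRAVIRINE = "nnrti",
    RILPIVIRINE = "nnrti",
    # protease inhibitors
    DRV = "pi", ATV = "pi", LPV = "pi", FPV = "pi", SQV = "pi", TPV = "pi",
    IDV = "pi", NFV = "pi",
    DARUNAVIR = "pi", ATAZANAVIR = "pi", LOPINAVIR = "pi",
    FOSAMPRENAVIR = "pi", SAQUINAVIR = "pi", TIPRANAVIR = "pi",
    # booster
    RTV = "booster", RITONAVIR = "booster", R = "booster",
    # integrase inhibitors and entry inhibitors fall to "other" classes
    RAL = "insti", DTG = "insti", EVG = "insti",
    MVC = "other", T20 = "other"
  )
}

#' Classify a drug combination into the five regimen types
#'
#' A regimen is `TDF_rbPI` when it contains tenofovir together with a
#' ritonavir-boosted protease inhibitor (any PI plus ritonavir), `TDF_NNRTI`
#' when it contains tenofovir and an NNRTI without a boosted PI, the analogous
#' `noTDF_*` types without tenofovir, and `OTHER` for any remaining
#' combination (e.g. integrase-inhibitor based, or an unboosted PI without an
#' NNRTI). A boosted PI takes precedence when both a boosted PI and an NNRTI
#' are present.
#'
#' @param components character vector of drug codes for one regimen, or a
#'   single string with components separated by `+`, `/` or whitespace.
#' @param warn_unknown warn when a code is absent from [arv_drug_classes()]
#'   (classification proceeds on the known components).
#' @return Length-1 factor with levels [regimen_levels()].
#' @examples
#' classify_regimen(c("TDF", "FTC", "DRV", "RTV"))
#' classify_regimen("ABC+3TC+EFV")
#' @export
classify_regimen <- function(components, warn_unknown = TRUE) {
  if (length(components) == 1 && grepl("[+/ ]", components)) {
    components <- strsplit(components, "[+/ ]+")[[1]]
  }
  components <- toupper(trimws(components))
  components <- components[nzchar(components)]
  if (length(components) == 0) {
    stop("empty drug component set", call. = FALSE)
  }
  lookup <- arv_drug_classes()
  known <- components %in% names(lookup)
  if (any(!known) && isTRUE(warn_unknown)) {
    warning("unknown drug code(s) ignored: ",
            paste(components[!known], collapse = ", "), call. = FALSE)
  }
  cls <- lookup[components[known]]
  has_tdf <- "TDF" %in% components[known]
  has_bpi <- any(cls == "pi") && any(cls == "booster")
  has_nnrti <- any(cls == "nnrti")
  type <- if (has_tdf && has_bpi) {
    "TDF_rbPI"
  } else if (has_tdf && has_nnrti) {
    "TDF_NNRTI"
  } else if (has_bpi) {
    "noTDF_rbPI"
  } else if (has_nnrti) {
    "noTDF_NNRTI"
  } else {
    "OTHER"
  }
  regimen_factor(type)
}

#' Vectorised regimen classification for an interval table
#'
#' @param regimens tibble with a `components` column (strings such as
#'   `"TDF+FTC+EFV"`); a pre-existing `regimen` column is kept as-is.
#' @inheritParams classify_regimen
#' @return The input with a `regimen` factor column added.
#' @export
classify_regimen_table <- function(regimens, warn_unknown = FALSE) {
  if ("regimen" %in% names(regimens)) {
    regimens$regimen <- regimen_factor(regimens$regimen)
    return(regimens)
  }
  combos <- unique(regimens$components)
  cls <- vapply(combos, function(x) {
    as.character(classify_regimen(x, warn_unknown = warn_unknown))
  }, character(1))
  regimens$regimen <- regimen_factor(cls[match(regimens$components, combos)])
  regimens
}
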