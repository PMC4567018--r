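#' Scored prognostic factors and their levels
#'
#' The eight pretreatment factors used to build the prognostic score,
#' each with its ordered levels (better-prognosis level conventions
#' follow the published coding: QOL deficit at <= 50, tumor size cut at
#' <= 2 cm, ECOG 0-1 vs 2-4, age bins left-closed/right-open).
#'
#' @return Named list mapping each coded-factor column name to its
#'   character vector of levels.
#' @export
score_factor_levels <- function() {
  list(
    qol_level     = c("nondeficit", "deficit"),
    age_level     = c("lt60", "60to70", "70to80", "ge80"),
    sex_level     = c("female", "male"),
    ecog_level    = c("ps01", "ps234"),
    smoking_level = c("quit", "kept_smoking"),
    size_level    = c("le2cm", "gt2cm"),
    nodal_level   = c("none", "ipsi_hilar", "ipsi_mediastinal",
                      "contralateral_mediastinal"),
    mets_level    = c("absent", "present")
  )
}

#' Reference level of each scored factor for Cox modelling
#'
#' Reference levels match the published multivariate model: hazard
#' ratios are reported for the remaining levels against these.
#'
#' @return Named character vector (factor column -> reference level).
#' @export
score_factor_reference <- function() {
  c(
    qol_level     = "nondeficit",
    age_level     = "ge80",
    sex_level     = "male",
    ecog_level    = "ps234",
    smoking_level = "kept_smoking",
    size_level    = "gt2cm",
    nodal_level   = "contralateral_mediastinal",
    mets_level    = "present"
  )
}

#' Names of the eight scored factor columns
#' @return Character vector of coded-factor column names.
#' @export
score_factor_names <- function() names(score_factor_levels())

# Human-readable labels used in exported tables.
factor_display_names <- c(
  qol_level     = "QOL",
  age_level     = "Age, years",
  sex_level     = "Sex",
  ecog_level    = "ECOG performance score",
  smoking_level = "Smoking cessation",
  size_level    = "Tumor size",
  nodal_level   = "Regional nodal involvement",
  mets_level    = "Distant metastasis",
  tumor_size    = "Tumor diameter (cm)"
)
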