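#' Default column mapping for cohort files
#'
#' Maps the canonical patient-record fields onto the column names used
#' in a cohort CSV. Override entries to adapt an external cohort without
#' touching code, or store the mapping in a YAML/JSON file and pass its
#' path to [read_cohort()].
#'
#' @param ... Named overrides, e.g. `age = "age_years"`.
#' @return Named character vector (canonical field -> file column).
#' @export
#' @examples
#' cohort_columns(qol = "overall_qol")
cohort_columns <- function(...) {
  map <- c(
    patient_id = "patient_id", age = "age", sex = "sex", qol = "qol",
    ecog = "ecog", smoking_cessation = "smoking_cessation",
    tumor_size = "tumor_size", nodal = "nodal", mets = "mets",
    time = "time", event = "event"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad)) stop("unknown cohort fields: ", paste(bad, collapse = ", "))
    map[names(dots)] <- dots
  }
  map
}

read_column_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    cfg <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
           else yaml::read_yaml(config)
    return(do.call(cohort_columns, as.list(unlist(cfg))))
  }
  if (is.null(config)) return(cohort_columns())
  do.call(cohort_columns, as.list(config))
}

sex_values     <- c("female", "male")
smoking_values <- c("quit", "kept_smoking")
nodal_values   <- c("none", "ipsi_hilar", "ipsi_mediastinal",
                    "contralateral_mediastinal")
mets_values    <- c("absent", "present")

# Validate one raw row; returns list(record=..., reason=NULL) or
# list(record=NULL, reason="..."). Blank/NA ecog is a permitted missing.
validate_row <- function(row) {
  num <- function(x) suppressWarnings(as.numeric(x))
  reason <- NULL
  chk <- function(ok, why) if (is.null(reason) && !isTRUE(ok)) reason <<- why

  age  <- num(row[["age"]]);        chk(!is.na(age) && age >= 0, "age unparseable or negative")
  sex  <- tolower(trimws(row[["sex"]]));   chk(sex %in% sex_values, "sex not female/male")
  qol  <- num(row[["qol"]])
  chk(!is.na(qol), "qol unparseable")
  chk(is.na(qol) || (qol >= 0 && qol <= 100), "qol out of range")
  ecog_raw <- trimws(as.character(row[["ecog"]]))
  ecog_blank <- is.na(ecog_raw) || !nzchar(ecog_raw) || toupper(ecog_raw) == "NA"
  ecog <- if (ecog_blank) NA_real_ else num(ecog_raw)
  if (!ecog_blank) chk(!is.na(ecog) && ecog %in% 0:4, "ecog not in 0..4")
  smk  <- tolower(trimws(row[["smoking_cessation"]]))
  chk(smk %in% smoking_values, "smoking_cessation not quit/kept_smoking")
  size <- num(row[["tumor_size"]]); chk(!is.na(size) && size >= 0, "tumor_size unparseable or negative")
  nod  <- tolower(trimws(row[["nodal"]])); chk(nod %in% nodal_values, "nodal level unrecognized")
  met  <- tolower(trimws(row[["mets"]])); chk(met %in% mets_values, "mets not absent/present")
  tim  <- num(row[["time"]]);       chk(!is.na(tim) && tim > 0, "time not strictly positive")
  evr  <- tolower(trimws(as.character(row[["event"]])))
  ev <- if (evr %in% c("death", "1", "true")) TRUE
        else if (evr %in% c("censored", "0", "false")) FALSE else NA
  chk(!is.na(ev), "event not death/censored")

  if (!is.null(reason)) return(list(record = NULL, reason = reason))
  list(record = data.frame(
    patient_id = as.character(row[["patient_id"]]), age = age, sex = sex,
    qol = qol, ecog = ecog, smoking_cessation = smk, tumor_size = size,
    nodal = nod, mets = met, time = tim, event = ev,
    stringsAsFactors = FALSE
  ), reason = NULL)
}

#' Read a patient cohort from a delimited file
#'
#' Reads one row per patient, validates each row against the
#' patient-record invariants (QOL in 0-100, strictly positive follow-up,
#' recognized factor levels, ECOG in 0-4 when present) and reports
#' rejected rows with reasons as well as per-column missing-value
#' counts. A blank ECOG cell is a permitted missing value; any other
#' invariant violation rejects the row.
#'
#' @param path Path to the CSV file.
#' @param columns Column mapping as from [cohort_columns()], or a path
#'   to a YAML/JSON file holding one.
#' @param delim Field delimiter (default comma).
#' @return An object of class `lung_cohort`: list with `patients` (one
#'   validated row per accepted patient), `rejects` (row index + reason)
#'   and `missing` (named count of missing values per field among
#'   accepted rows).
#' @export
read_cohort <- function(path, columns = cohort_columns(), delim = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  map <- read_column_config(columns)
  raw <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols))
    stop_lungscore(
      paste0("required column(s) missing from ", path, ": ",
             paste(sprintf("%s (field %s)", missing_cols, names(missing_cols)),
                   collapse = ", ")),
      "lungscore_missing_column")

  recs <- vector("list", nrow(raw))
  rej_row <- integer(0); rej_reason <- character(0)
  for (i in seq_len(nrow(raw))) {
    row <- as.list(raw[i, map, drop = FALSE])
    names(row) <- names(map)
    v <- validate_row(row)
    if (is.null(v$record)) {
      rej_row <- c(rej_row, i); rej_reason <- c(rej_reason, v$reason)
    } else recs[[i]] <- v$record
  }
  patients <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(patients)) patients <- validate_row(list())$record[0, ]
  rownames(patients) <- NULL
  missing <- vapply(patients, function(col) sum(is.na(col)), integer(1))
  structure(
    list(patients = patients,
         rejects = data.frame(row = rej_row, reason = rej_reason,
                              stringsAsFactors = FALSE),
         missing = missing),
    class = "lung_cohort")
}

#' @export
print.lung_cohort <- function(x, ...) {
  cat(sprintf("<lung_cohort> %d patients (%d rejected rows)\n",
              nrow(x$patients), nrow(x$rejects)))
  mis <- x$missing[x$missing > 0]
  if (length(mis))
    cat("missing values:",
        paste(sprintf("%s: %d", names(mis), mis), collapse = ", "), "\n")
  invisible(x)
}

as_patient_frame <- function(cohort) {
  if (inherits(cohort, "lung_cohort")) cohort$patients else as.data.frame(cohort)
}

#' Code raw patient covariates into scored factor levels
#'
#' Deterministic recoding of raw covariates into the eight factor levels
#' used by the score: QOL deficit iff qol <= 50; age bins `[0,60)`,
#' `[60,70)`, `[70,80)`, `[80,Inf)`; ECOG 0-1 vs 2-4 (missing ECOG
#' propagates to a missing level); quit vs kept smoking; tumor size
#' <= 2 cm vs > 2 cm; the four ordered nodal levels; metastasis
#' absent/present.
#'
#' @param cohort A `lung_cohort` or a patient data frame.
#' @return Data frame with `patient_id`, the eight `*_level` factor
#'   columns, the raw `tumor_size`, and `time`/`event`.
#' @export
#' @examples
#' pts <- data.frame(patient_id = "a", age = 60, sex = "female", qol = 50,
#'   ecog = 0, smoking_cessation = "quit", tumor_size = 2, nodal = "none",
#'   mets = "absent", time = 3, event = TRUE)
#' code_factors(pts)[, c("qol_level", "age_level", "size_level")]
code_factors <- function(cohort) {
  p <- as_patient_frame(cohort)
  lv <- score_factor_levels()
  fac <- function(x, levels) factor(x, levels = levels)
  age_level <- cut(p$age, breaks = c(-Inf, 60, 70, 80, Inf), right = FALSE,
                   labels = lv$age_level)
  out <- data.frame(
    patient_id = p$patient_id,
    qol_level   = fac(ifelse(p$qol <= 50, "deficit", "nondeficit"), lv$qol_level),
    age_level   = factor(as.character(age_level), levels = lv$age_level),
    sex_level   = fac(p$sex, lv$sex_level),
    ecog_level  = fac(ifelse(is.na(p$ecog), NA,
                             ifelse(p$ecog <= 1, "ps01", "ps234")), lv$ecog_level),
    smoking_level = fac(p$smoking_cessation, lv$smoking_level),
    size_level  = fac(ifelse(p$tumor_size <= 2, "le2cm", "gt2cm"), lv$size_level),
    nodal_level = fac(p$nodal, lv$nodal_level),
    mets_level  = fac(p$mets, lv$mets_level),
    tumor_size  = p$tumor_size,
    time = p$time, event = p$event,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Demographic summary of a cohort
#'
#' Per-variable level counts and percentages (percentages over
#' non-missing values, with missing counts reported separately), plus
#' mean, SD, median, quartiles and range for tumor size.
#'
#' @param cohort A `lung_cohort` or patient data frame.
#' @return Object of class `cohort_summary`: list with `categorical`
#'   (variable, level, n, percent), `tumor_size` (numeric summary) and
#'   `missing` counts.
#' @export
summarize_demographics <- function(cohort) {
  p <- as_patient_frame(cohort)
  if (nrow(p) == 0) stop_lungscore("empty cohort", "lungscore_empty_cohort")
  coded <- code_factors(p)
  rows <- list()
  for (v in score_factor_names()) {
    x <- coded[[v]]
    tab <- table(x[!is.na(x)])
    rows[[v]] <- data.frame(
      variable = factor_display_names[[v]],
      level = names(tab),
      n = as.integer(tab),
      percent = round(100 * as.integer(tab) / sum(tab), 1),
      stringsAsFactors = FALSE)
  }
  categorical <- do.call(rbind, rows)
  rownames(categorical) <- NULL
  ts <- p$tumor_size
  tumor_size <- data.frame(
    n = length(ts), mean = mean(ts), sd = stats::sd(ts),
    median = stats::median(ts),
    q1 = unname(stats::quantile(ts, 0.25)),
    q3 = unname(stats::quantile(ts, 0.75)),
    min = min(ts), max = max(ts))
  missing <- vapply(coded[score_factor_names()],
                    function(col) sum(is.na(col)), integer(1))
  structure(list(categorical = categorical, tumor_size = tumor_size,
                 missing = missing, n = nrow(p)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort demographics (N = %d)\n", x$n))
  for (v in unique(x$categorical$variable)) {
    cat(v, "\n")
    sub <- x$categorical[x$categorical$variable == v, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-28s %5d (%.1f%%)\n", sub$level[i], sub$n[i], sub$percent[i]))
  }
  with(x$tumor_size, cat(sprintf(
    "Tumor size (cm): mean %.1f (SD %.1f), median %.1f, Q1 %.1f, Q3 %.1f, range %.1f-%.1f\n",
    mean, sd, median, q1, q3, min, max)))
  mis <- x$missing[x$missing > 0]
  if (length(mis))
    cat("Missing:", paste(sprintf("%s: %d", names(mis), mis), collapse = ", "), "\n")
  invisible(x)
}

#' Write a demographic summary to CSV
#' @param x A `cohort_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  num <- x$tumor_size
  extra <- data.frame(
    variable = "Tumor size (cm), distribution",
    level = c("mean", "sd", "median", "q1", "q3", "min", "max"),
    n = NA_integer_,
    percent = NA_real_,
    value = as.numeric(num[1, c("mean", "sd", "median", "q1", "q3", "min", "max")]),
    stringsAsFactors = FALSE)
  cats <- x$categorical
  cats$value <- NA_real_
  utils::write.csv(rbind(cats, extra), path, row.names = FALSE)
  invisible(path)
}
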