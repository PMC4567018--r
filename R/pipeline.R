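#' Configuration for the full scoring pipeline
#'
#' @param input Path to the cohort CSV.
#' @param columns Column mapping ([cohort_columns()] or a YAML/JSON
#'   path).
#' @param factors Scored factor set (default: the eight factors; drop
#'   `sex_level` here to reproduce the seven-factor variant).
#' @param rounding Rounding policy for [level_score()].
#' @param ties Cox tie handling.
#' @param p_enter,p_stay Stepwise thresholds.
#' @param bootstrap_B Number of bootstrap resamples.
#' @param seed Root seed for the bootstrap.
#' @param scheme Category scheme name or YAML path.
#' @param out_dir Output directory for the exported tables.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, columns = cohort_columns(),
                            factors = score_factor_names(),
                            rounding = "two_stage", ties = "breslow",
                            p_enter = 0.05, p_stay = 0.05,
                            bootstrap_B = 1000, seed = 1L,
                            scheme = "category4", out_dir = "lungscore-out") {
  stopifnot(bootstrap_B >= 1)
  # fail fast on a missing preset rather than mid-pipeline
  invisible(category_scheme(scheme))
  structure(list(input = input, columns = columns, factors = factors,
                 rounding = rounding, ties = ties, p_enter = p_enter,
                 p_stay = p_stay, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), scheme = scheme,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full scoring pipeline on a cohort file
#'
#' Executes, in order: cohort ingestion and demographics, univariate
#' Cox screen, multivariate Cox fit, score-table construction,
#' per-total-score survival report, category report, and the two
#' bootstrap validations; writes each as CSV into the output directory
#' together with a JSON run manifest (config echo, seed, package
#' version, row counts). Any stage failure is re-signalled with the
#' failing stage named; partial outputs are retained.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the output paths and key objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_lungscore(paste0("stage '", name, "' failed: ",
                            conditionMessage(e)),
                     "lungscore_stage_failure", stage = name)
    })
  }
  paths <- character(0)

  cohort <- stage("cohort_data", read_cohort(config$input, config$columns))
  demo <- stage("cohort_data", summarize_demographics(cohort))
  paths["demographics"] <- write_summary(demo, out("demographics.csv"))
  coded <- stage("cohort_data", code_factors(cohort))

  uv <- stage("survival_core",
              univariate_screen(coded, c(config$factors, "tumor_size"),
                                ties = config$ties))
  paths["univariate"] <- write_cox_table(uv, out("univariate.csv"))
  mv <- stage("survival_core",
              multivariate_fit(coded, config$factors, ties = config$ties))
  paths["multivariate"] <- write_cox_table(mv, out("multivariate.csv"))

  stab <- stage("score_engine",
                build_score_table(coded, config$factors,
                                  policy = config$rounding))
  utils::write.csv(as.data.frame(stab), out("score_table.csv"),
                   row.names = FALSE)
  paths["score_table"] <- out("score_table.csv")

  scored <- complete_for(coded, config$factors)
  totals <- stage("score_engine", total_score(scored, stab))
  per_score <- stage("score_engine",
                     per_total_score_report(totals, scored$time, scored$event))
  utils::write.csv(per_score, out("per_score.csv"), row.names = FALSE)
  paths["per_score"] <- out("per_score.csv")

  scheme <- category_scheme(config$scheme)
  # observed totals may fall outside the published bins on other
  # cohorts; widen the outer bins to the observed range if needed
  scheme_used <- widen_scheme(scheme, range(totals))
  cats <- stage("score_engine",
                category_report(totals, scored$time, scored$event,
                                scheme_used, ties = config$ties))
  utils::write.csv(as.data.frame(cats), out("categories.csv"),
                   row.names = FALSE)
  paths["categories"] <- out("categories.csv")

  incl <- stage("validation_bootstrap",
                bootstrap_model_inclusion(coded, config$factors,
                                          B = config$bootstrap_B,
                                          p_enter = config$p_enter,
                                          p_stay = config$p_stay,
                                          seed = config$seed,
                                          ties = config$ties))
  utils::write.csv(as.data.frame(incl), out("bootstrap_inclusion.csv"),
                   row.names = FALSE)
  paths["bootstrap_inclusion"] <- out("bootstrap_inclusion.csv")
  rates <- stage("validation_bootstrap",
                 bootstrap_level_rates(coded, config$factors,
                                       B = config$bootstrap_B,
                                       seed = config$seed))
  utils::write.csv(as.data.frame(rates), out("bootstrap_rates.csv"),
                   row.names = FALSE)
  paths["bootstrap_rates"] <- out("bootstrap_rates.csv")

  manifest <- list(
    config = config[setdiff(names(config), "columns")],
    columns = as.list(read_column_config(config$columns)),
    package_version = as.character(utils::packageVersion("lungscore")),
    n_read = nrow(cohort$patients), n_rejected = nrow(cohort$rejects),
    n_scored = nrow(scored), seed = config$seed)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["manifest"] <- out("manifest.json")

  invisible(list(paths = paths, cohort = cohort, coded = coded, uv = uv,
                 mv = mv, score_table = stab, totals = totals,
                 per_score = per_score, categories = cats,
                 inclusion = incl, rates = rates))
}

# Extend the first/last bin of a scheme so it covers the observed
# total-score range (pipeline convenience; categorize() itself never
# clamps).
widen_scheme <- function(scheme, observed_range) {
  s <- scheme
  if (observed_range[1] < s$lo[1]) {
    s$lo[1] <- observed_range[1]
    s$label[1] <- paste0(s$lo[1], "-", s$hi[1])
  }
  k <- nrow(s)
  if (observed_range[2] > s$hi[k]) {
    s$hi[k] <- observed_range[2]
    s$label[k] <- paste0(s$lo[k], "-", s$hi[k])
  }
  s
}

#' Score a single patient profile
#'
#' Computes the total score for one fully specified eight-factor
#' profile, its category under a scheme, and that bin's stored 5-year
#' survival summary. Works with no cohort at all via the packaged
#' reference score table.
#'
#' @param profile Named list/vector of factor levels, e.g.
#'   `list(qol_level = "nondeficit", age_level = "lt60", ...)`.
#' @param table A `score_table` (default: the packaged reference).
#' @param scheme Category scheme (name or object).
#' @return List with `total`, `bin`, `five_year_rate`, `ci`.
#' @export
#' @examples
#' best <- list(qol_level = "nondeficit", age_level = "lt60",
#'   sex_level = "female", ecog_level = "ps01", smoking_level = "quit",
#'   size_level = "le2cm", nodal_level = "none", mets_level = "absent")
#' score_patient(best)
score_patient <- function(profile, table = reference_score_table(),
                          scheme = "category4") {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  factors <- unique(table$factor)
  missing <- setdiff(factors, names(profile))
  missing <- union(missing,
                   names(profile)[vapply(profile, function(x)
                     is.null(x) || is.na(x), logical(1))])
  missing <- intersect(missing, factors)
  if (length(missing))
    stop_lungscore(paste0("incomplete profile; missing factor(s): ",
                          paste(sub("_level$", "", missing), collapse = ", ")),
                   "lungscore_incomplete_profile")
  lv <- score_factor_levels()
  for (f in factors)
    if (!profile[[f]] %in% lv[[f]])
      stop("unknown level '", profile[[f]], "' for ", f)
  row <- as.data.frame(lapply(profile[factors], as.character),
                       stringsAsFactors = FALSE)
  names(row) <- factors
  total <- total_score(row, table)
  bin <- as.character(categorize(total, scheme))
  i <- match(bin, scheme$label)
  list(total = total, bin = bin,
       five_year_rate = scheme$five_year_rate[i],
       ci = c(scheme$ci_lower[i], scheme$ci_upper[i]))
}
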