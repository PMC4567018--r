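#' Default covariate marginals for the synthetic cohort
#'
#' Level probabilities for the eight scored factors, matching the
#' published cohort's demographic table (ECOG among its non-missing
#' records). Variables are sampled independently.
#'
#' @return Named list of named probability vectors.
#' @export
default_marginals <- function() {
  list(
    qol_level     = c(nondeficit = 1045, deficit = 229) / 1274,
    age_level     = c(lt60 = 300, `60to70` = 427, `70to80` = 440, ge80 = 107) / 1274,
    sex_level     = c(female = 604, male = 670) / 1274,
    ecog_level    = c(ps01 = 1094, ps234 = 156) / 1250,
    smoking_level = c(quit = 1217, kept_smoking = 57) / 1274,
    size_level    = c(le2cm = 479, gt2cm = 795) / 1274,
    nodal_level   = c(none = 927, ipsi_hilar = 123, ipsi_mediastinal = 196,
                      contralateral_mediastinal = 28) / 1274,
    mets_level    = c(absent = 1193, present = 81) / 1274
  )
}

#' Default log hazard ratios for the synthetic cohort
#'
#' Per-level log hazard ratios versus each factor's reference level,
#' set to the log of the published multivariate hazard ratios.
#'
#' @return Named list: factor -> named numeric vector over non-reference
#'   levels.
#' @export
default_log_hr <- function() {
  list(
    qol_level     = c(deficit = log(1.841)),
    age_level     = c(lt60 = log(0.395), `60to70` = log(0.489),
                      `70to80` = log(0.795)),
    sex_level     = c(female = log(0.782)),
    ecog_level    = c(ps01 = log(0.448)),
    smoking_level = c(quit = log(0.496)),
    size_level    = c(le2cm = log(0.702)),
    nodal_level   = c(none = log(0.259), ipsi_hilar = log(0.402),
                      ipsi_mediastinal = log(0.574)),
    mets_level    = c(absent = log(0.274))
  )
}

# Exponential rate (per year) for the all-reference profile, calibrated
# once by exact enumeration over the covariate cells so that the pooled
# censoring-free 5-year survival under the default marginals and log
# hazard ratios is 57%.
default_baseline_rate <- 8.7035296

#' Configuration for the synthetic cohort generator
#'
#' @param n Cohort size (>= 1).
#' @param marginals Per-variable level probabilities (must sum to 1).
#' @param log_hr Per-level log hazard ratios vs reference.
#' @param baseline Exponential event rate per year for the
#'   all-reference profile.
#' @param admin_horizon Administrative censoring time in years
#'   (must exceed 5 so 5-year rates are estimable).
#' @param dropout_max Upper bound of the uniform random dropout time.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 1274, marginals = default_marginals(),
                              log_hr = default_log_hr(),
                              baseline = default_baseline_rate,
                              admin_horizon = 10, dropout_max = 15,
                              seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (baseline <= 0) stop("baseline rate must be positive")
  if (admin_horizon <= 5) stop("admin_horizon must exceed 5 years")
  lv <- score_factor_levels()
  for (v in score_factor_names()) {
    pm <- marginals[[v]]
    if (is.null(pm) || abs(sum(pm) - 1) > 1e-9)
      stop("marginals for ", v, " must be supplied and sum to 1")
    if (!setequal(names(pm), lv[[v]]))
      stop("marginals for ", v, " must name levels ",
           paste(lv[[v]], collapse = ", "))
  }
  structure(list(n = as.integer(n), marginals = marginals, log_hr = log_hr,
                 baseline = baseline, admin_horizon = admin_horizon,
                 dropout_max = dropout_max, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Linear predictor lookup: log HR of level l of factor v (0 for the
# reference level).
lhr_of <- function(log_hr, v, l) {
  x <- log_hr[[v]][l]
  ifelse(is.na(x), 0, x)
}

#' Exact per-level 5-year survival under a generator configuration
#'
#' Marginal censoring-free 5-year survival for each factor level,
#' computed by exact enumeration over all covariate cells (the
#' covariates are independent, so the cell distribution factorizes).
#'
#' @param config A `cohort_sim_config`.
#' @param horizon Horizon in years (default 5).
#' @return Data frame (factor, level, true_rate in percent).
#' @export
true_level_rates <- function(config, horizon = 5) {
  m <- config$marginals
  grid <- expand.grid(lapply(m, function(p) names(p)),
                      stringsAsFactors = FALSE)
  pr <- rep(1, nrow(grid)); eta <- rep(0, nrow(grid))
  for (v in names(m)) {
    pr <- pr * m[[v]][grid[[v]]]
    eta <- eta + lhr_of(config$log_hr, v, grid[[v]])
  }
  surv <- exp(-horizon * config$baseline * exp(eta))
  rows <- list()
  for (v in names(m)) for (l in names(m[[v]])) {
    sel <- grid[[v]] == l
    rows[[paste(v, l)]] <- data.frame(
      factor = v, level = l,
      true_rate = 100 * sum(pr[sel] * surv[sel]) / sum(pr[sel]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Continuous values drawn within a sampled level's interval. ECOG 2/3/4
# split follows the published within-level mix; tumor sizes above 2 cm
# decay exponentially to mimic the right-skewed diameter distribution.
draw_raw_within_level <- function(coded_levels, n) {
  age <- numeric(n); qol <- integer(n); ecog <- integer(n); size <- numeric(n)
  al <- coded_levels$age_level
  age[al == "lt60"]   <- runif(sum(al == "lt60"), 40, 60)
  age[al == "60to70"] <- runif(sum(al == "60to70"), 60, 70)
  age[al == "70to80"] <- runif(sum(al == "70to80"), 70, 80)
  age[al == "ge80"]   <- runif(sum(al == "ge80"), 80, 95)
  ql <- coded_levels$qol_level
  qol[ql == "nondeficit"] <- sample(51:100, sum(ql == "nondeficit"), TRUE)
  qol[ql == "deficit"]    <- sample(0:50, sum(ql == "deficit"), TRUE)
  el <- coded_levels$ecog_level
  ecog[el == "ps01"]  <- sample(0:1, sum(el == "ps01"), TRUE)
  ecog[el == "ps234"] <- sample(2:4, sum(el == "ps234"), TRUE,
                                prob = c(117, 33, 6) / 156)
  sl <- coded_levels$size_level
  size[sl == "le2cm"] <- runif(sum(sl == "le2cm"), 0.2, 2.0)
  size[sl == "gt2cm"] <- pmin(2.0 + rexp(sum(sl == "gt2cm"), 1 / 1.5), 19)
  list(age = round(age, 1), qol = qol, ecog = ecog, size = round(size, 2))
}

#' Generate a synthetic patient cohort
#'
#' Draws the eight factor levels independently from the configured
#' marginals; survival times are exponential with rate
#' `baseline * exp(sum of the patient's log hazard ratios)`; censoring
#' is the minimum of the administrative horizon and a uniform dropout
#' time; continuous age, QOL, ECOG and tumor size are drawn within the
#' sampled level's interval. Deterministic given the config seed.
#'
#' @param config A `cohort_sim_config`.
#' @return List with `cohort` (a patient data frame accepted by
#'   [code_factors()] and writable by [write_cohort_csv()]) and
#'   `manifest` (the realized config plus exact per-level 5-year
#'   survival).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n
  m <- config$marginals
  lev <- lapply(score_factor_names(), function(v)
    sample(names(m[[v]]), n, TRUE, prob = m[[v]]))
  names(lev) <- score_factor_names()
  eta <- rep(0, n)
  for (v in score_factor_names()) eta <- eta + lhr_of(config$log_hr, v, lev[[v]])
  raw <- draw_raw_within_level(lev, n)
  t_event <- rexp(n, config$baseline * exp(eta))
  t_cens <- pmin(config$admin_horizon, runif(n, 0, config$dropout_max))
  time <- pmax(pmin(t_event, t_cens), 1e-6)
  event <- t_event <= t_cens

  cohort <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = raw$age,
    sex = lev$sex_level,
    qol = raw$qol,
    ecog = raw$ecog,
    smoking_cessation = lev$smoking_level,
    tumor_size = ifelse(lev$size_level == "le2cm",
                        pmin(raw$size, 2), pmax(raw$size, 2.01)),
    nodal = lev$nodal_level,
    mets = lev$mets_level,
    time = round(time, 6),
    event = event,
    stringsAsFactors = FALSE)
  manifest <- list(
    config = list(n = n, marginals = m, log_hr = config$log_hr,
                  baseline = config$baseline,
                  admin_horizon = config$admin_horizon,
                  dropout_max = config$dropout_max, seed = config$seed),
    true_rates = true_level_rates(config),
    n_events = sum(event))
  list(cohort = cohort, manifest = manifest)
}

#' Write a cohort to CSV in the dialect read_cohort() consumes
#'
#' Locale-independent formatting (C numeric formatting, fixed column
#' order) so identical cohorts produce byte-identical files.
#'
#' @param cohort Patient data frame.
#' @param path Output path.
#' @param manifest Optional manifest list written as JSON next to the
#'   cohort (same path with extension `.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, manifest = NULL) {
  out <- cohort
  out$event <- ifelse(as.logical(cohort$event), "death", "censored")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   na = "")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a deterministic suite of small cohort fixtures
#'
#' Tiny cohorts (n = 5, 20, 200 at fixed seeds) plus a hand-built
#' malformed-rows file (4 valid rows, 3 designed rejects: QOL out of
#' range, non-positive follow-up, unknown nodal level) for I/O tests.
#' Repeated invocation is byte-identical.
#'
#' @param out_dir Writable directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  paths <- character(0)
  for (n in c(5, 20, 200)) {
    g <- generate_cohort(cohort_sim_config(n = n, seed = 1000L + n))
    p <- file.path(out_dir, sprintf("cohort_n%d.csv", n))
    write_cohort_csv(g$cohort, p, manifest = g$manifest)
    paths[sprintf("n%d", n)] <- p
  }
  good <- generate_cohort(cohort_sim_config(n = 4, seed = 99L))$cohort
  bad <- good[c(1, 1, 1), ]
  bad$patient_id <- c("BAD1", "BAD2", "BAD3")
  bad$qol[1] <- 150                 # qol out of range
  bad$time[2] <- 0                  # non-positive follow-up
  bad$nodal[3] <- "everywhere"      # unknown nodal level
  p <- file.path(out_dir, "cohort_malformed.csv")
  write_cohort_csv(rbind(good, bad), p)
  paths["malformed"] <- p
  invisible(paths)
}
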