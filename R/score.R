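#' Convert a 5-year survival rate (percent) into an integer score
#'
#' The score for a factor level is its 5-year overall survival rate
#' divided by ten, as a whole digit. The default `"two_stage"` policy
#' first rounds the rate to the nearest whole percent (half away from
#' zero), then divides by ten and rounds again half away from zero:
#' this is the unique convention that reproduces every published
#' rate/score pair (e.g. an unrounded 64.8% prints as 65% and scores
#' 7, while a single-stage round of 6.48 would give 6). The simpler
#' `"round_once"` (round rate/10 directly) and `"floor"` policies are
#' available for sensitivity analysis.
#'
#' @param rate 5-year survival rate(s) in percent, in \\[0, 100\\].
#' @param policy Rounding policy; see Details.
#' @return Integer score(s).
#' @export
#' @examples
#' level_score(62)    # 6
#' level_score(24)    # 2
#' level_score(64.8)  # 7 (65 after whole-percent rounding)
level_score <- function(rate, policy = c("two_stage", "round_once", "floor")) {
  policy <- match.arg(policy)
  if (any(is.na(rate)) || any(rate < 0 | rate > 100))
    stop_lungscore("rate outside [0, 100]", "lungscore_bad_rate")
  s <- switch(policy,
    two_stage  = round_half_up(round_half_up(rate) / 10),
    round_once = round_half_up(rate / 10),
    floor      = floor(rate / 10))
  as.integer(s)
}

#' The packaged reference score table
#'
#' The published per-level 5-year survival rates and integer scores for
#' the eight prognostic factors, shipped as a preset so single patients
#' can be scored without any cohort data.
#'
#' @return A `score_table` data frame (factor, level, five_year_rate,
#'   score).
#' @export
reference_score_table <- function() {
  path <- system.file("extdata", "reference_score_table.csv",
                      package = "lungscore", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(tab, class = c("score_table", "data.frame"),
            policy = "two_stage", horizon = 5)
}

#' Build a score table from a coded cohort
#'
#' For each level of each scored factor, subsets the cohort to that
#' level, computes the 5-year Kaplan-Meier survival rate, and converts
#' it to an integer score with [level_score()].
#'
#' @param coded Coded cohort from [code_factors()] with `time`/`event`.
#' @param factors Factors to score (default: the eight scored factors).
#' @param horizon Rate horizon in years (default 5).
#' @param policy Rounding policy for [level_score()].
#' @return A `score_table` data frame (factor, level, n, events,
#'   five_year_rate, score).
#' @export
build_score_table <- function(coded, factors = score_factor_names(),
                              horizon = 5,
                              policy = c("two_stage", "round_once", "floor")) {
  policy <- match.arg(policy)
  lv <- score_factor_levels()
  rows <- list()
  for (f in factors) {
    for (l in lv[[f]]) {
      sel <- !is.na(coded[[f]]) & coded[[f]] == l
      if (!any(sel))
        stop_lungscore(paste0("no patients at level ", l, " of ", f),
                       "lungscore_empty_level")
      curve <- km_fit(coded$time[sel], coded$event[sel])
      rate <- suppressWarnings(rate_at(curve, horizon)$rate)
      rows[[paste(f, l)]] <- data.frame(
        factor = f, level = l, n = sum(sel),
        events = sum(coded$event[sel]),
        five_year_rate = rate,
        score = level_score(rate, policy),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("score_table", "data.frame"),
            policy = policy, horizon = horizon)
}

#' Total prognostic score per patient
#'
#' Sums the per-level scores of the scored factors for each patient.
#' Patients missing any scored factor cannot be scored: by default this
#' signals an error (complete-case scoring); with
#' `on_incomplete = "na"` such patients receive `NA` and can be
#' excluded by the caller.
#'
#' @param coded Coded cohort (or single coded row) from
#'   [code_factors()].
#' @param table A `score_table`.
#' @param on_incomplete `"error"` (default) or `"na"`.
#' @return Integer vector of total scores.
#' @export
total_score <- function(coded, table = reference_score_table(),
                        on_incomplete = c("error", "na")) {
  on_incomplete <- match.arg(on_incomplete)
  factors <- unique(table$factor)
  total <- rep(0L, nrow(coded))
  incomplete <- rep(FALSE, nrow(coded))
  for (f in factors) {
    key <- paste(f, as.character(coded[[f]]))
    lut <- stats::setNames(table$score[table$factor == f],
                           paste(f, table$level[table$factor == f]))
    s <- lut[key]
    incomplete <- incomplete | is.na(s)
    total <- total + ifelse(is.na(s), 0L, as.integer(s))
  }
  if (any(incomplete)) {
    if (on_incomplete == "error")
      stop_lungscore(
        paste0(sum(incomplete), " patient(s) incomplete for scoring"),
        "lungscore_incomplete_for_scoring")
    total[incomplete] <- NA_integer_
  }
  unname(total)
}

#' Load a total-score categorization scheme
#'
#' The four published categorization schemes ship as configuration
#' (`category1` ... `category4`), each an ordered list of inclusive
#' total-score ranges with the published per-bin 5-year survival
#' summaries; the highest bin is the reference.
#'
#' @param name Scheme name (`"category4"` is the headline scheme) or a
#'   path to a YAML file with the same structure.
#' @return Object of class `category_scheme`: data frame of bins
#'   (label, lo, hi, five_year_rate, ci_lower, ci_upper) with attribute
#'   `name`; the last row is the reference bin.
#' @export
category_scheme <- function(name = "category4") {
  if (file.exists(name)) {
    all <- yaml::read_yaml(name)
    if (length(all) == 1 && is.list(all[[1]]$bins %||% NULL)) {
      scheme <- all[[1]]; label <- names(all)[1]
    } else stop("scheme file must hold one named scheme with a 'bins' list")
  } else {
    path <- system.file("extdata", "category_schemes.yaml",
                        package = "lungscore", mustWork = TRUE)
    all <- yaml::read_yaml(path)
    if (!name %in% names(all))
      stop("unknown scheme '", name, "'; available: ",
           paste(names(all), collapse = ", "))
    scheme <- all[[name]]; label <- name
  }
  bins <- do.call(rbind, lapply(scheme$bins, function(b) data.frame(
    lo = b$lo, hi = b$hi, label = paste0(b$lo, "-", b$hi),
    five_year_rate = b$five_year_rate %||% NA_real_,
    ci_lower = if (!is.null(b$ci)) b$ci[[1]] else NA_real_,
    ci_upper = if (!is.null(b$ci)) b$ci[[2]] else NA_real_,
    stringsAsFactors = FALSE)))
  stopifnot(all(diff(bins$lo) > 0), all(bins$hi >= bins$lo),
            all(bins$lo[-1] == bins$hi[-nrow(bins)] + 1))
  structure(bins, class = c("category_scheme", "data.frame"), name = label)
}

#' Assign total scores to category bins
#'
#' @param total Integer total score(s).
#' @param scheme A `category_scheme` (or scheme name).
#' @return Character bin labels (`"lo-hi"`). Out-of-range totals are an
#'   error, never silently clamped.
#' @export
#' @examples
#' categorize(39, category_scheme("category4"))  # "38-43"
categorize <- function(total, scheme = category_scheme("category4")) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  idx <- findInterval(total, scheme$lo)
  bad <- idx == 0 | total > scheme$hi[pmax(idx, 1)]
  if (any(bad, na.rm = TRUE))
    stop_lungscore(
      paste0("total score(s) outside scheme range [", min(scheme$lo), ", ",
             max(scheme$hi), "]: ",
             paste(unique(total[which(bad)]), collapse = ", ")),
      "lungscore_score_out_of_range")
  out <- scheme$label[idx]
  out[is.na(total)] <- NA_character_
  factor(out, levels = scheme$label)
}

#' Survival report by total-score category
#'
#' Per-bin N, events, Kaplan-Meier median survival, and 5-year rate
#' with Greenwood CI; an overall log-rank test across bins; and a
#' univariate Cox hazard ratio for each bin against the reference
#' (highest) bin. Bins with zero events have their hazard ratio
#' omitted and flagged.
#'
#' @param total Integer total scores.
#' @param time,event Follow-up times and event indicators.
#' @param scheme A `category_scheme`.
#' @param ties Tie handling for the per-bin Cox fit.
#' @return Object of class `category_report`: data frame of per-bin
#'   results with the log-rank test as attribute `logrank`.
#' @export
category_report <- function(total, time, event,
                            scheme = category_scheme("category4"),
                            ties = "breslow", horizon = 5) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  bin <- categorize(total, scheme)
  occupied <- levels(bin)[table(bin) > 0]
  if (length(occupied) < 2)
    stop_lungscore(">=2 nonempty bins required", "lungscore_too_few_bins")
  lr <- logrank(time, event, droplevels(bin))

  ref_label <- scheme$label[nrow(scheme)]
  rows <- list()
  for (l in levels(bin)) {
    sel <- !is.na(bin) & bin == l
    if (!any(sel)) next
    curve <- km_fit(time[sel], event[sel])
    r5 <- suppressWarnings(rate_at(curve, horizon))
    med <- km_median(curve)
    rows[[l]] <- data.frame(
      bin = l, n = sum(sel), events = sum(event[sel]),
      median_years = med$median,
      five_year_rate = r5$rate, rate_lower = r5$lower, rate_upper = r5$upper,
      hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_,
      wald_p = NA_real_, zero_events = sum(event[sel]) == 0,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # per-bin UV Cox vs the reference bin, skipping zero-event bins
  if (ref_label %in% tab$bin) {
    for (l in setdiff(tab$bin, ref_label)) {
      if (tab$zero_events[tab$bin == l]) next
      sel <- !is.na(bin) & bin %in% c(l, ref_label)
      X <- matrix(as.numeric(bin[sel] == l), ncol = 1,
                  dimnames = list(NULL, paste0("bin=", l)))
      f <- tryCatch(cox_fit(X, time[sel], event[sel], ties = ties),
                    error = function(e) NULL)
      if (is.null(f)) next
      i <- which(tab$bin == l)
      tab$hr[i] <- unname(f$hr); tab$hr_lower[i] <- f$ci95[, "lower"]
      tab$hr_upper[i] <- f$ci95[, "upper"]; tab$wald_p[i] <- unname(f$wald_p)
    }
  }
  structure(tab, class = c("category_report", "data.frame"),
            logrank = lr, scheme = attr(scheme, "name"))
}

#' Survival report per distinct total score
#'
#' For each observed total score: N, Kaplan-Meier median survival with
#' CI (`NA` when the curve never reaches 0.5 -- "not attained"), and the
#' 5-year survival rate. Rows are emitted only for observed totals.
#'
#' @inheritParams category_report
#' @param horizon Rate horizon in years.
#' @return Data frame with one row per observed total score.
#' @export
per_total_score_report <- function(total, time, event, horizon = 5) {
  rows <- list()
  for (s in sort(unique(total[!is.na(total)]))) {
    sel <- !is.na(total) & total == s
    curve <- km_fit(time[sel], event[sel])
    med <- km_median(curve)
    r <- suppressWarnings(rate_at(curve, horizon))
    rows[[as.character(s)]] <- data.frame(
      total_score = s, n = sum(sel),
      median_years = med$median, median_lower = med$lower,
      median_upper = med$upper,
      five_year_rate = r$rate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> policy = %s, horizon = %s y\n",
              attr(x, "policy"), attr(x, "horizon")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf("Survival by total-score category (%s)\n", attr(x, "scheme")))
  print.data.frame(x, digits = 4, ...)
  lr <- attr(x, "logrank")
  cat(sprintf("Log-rank across bins: chi-square = %.2f on %d df, p = %.3g\n",
              lr$chi_square, lr$df, lr$p_value))
  invisible(x)
}
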