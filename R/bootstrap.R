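# One root seed fans out into per-resample substream seeds so that the
# first b resamples are identical whatever the total B.
substream_seeds <- function(seed, B) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B, replace = TRUE)
}

#' Bootstrap variable-inclusion frequencies of the stepwise Cox model
#'
#' Draws `B` resamples with replacement of the original cohort size,
#' runs [stepwise_cox()] on each, and tallies how often each candidate
#' factor is selected. Resamples where a factor collapses to a single
#' level skip that factor (counted in `skipped`); resamples whose
#' stepwise run fails are excluded from the denominator and counted.
#'
#' @param coded Coded cohort with `time`/`event`.
#' @param candidates Candidate factor columns.
#' @param B Number of bootstrap resamples.
#' @param p_enter,p_stay Stepwise thresholds.
#' @param seed Root seed; results are reproducible given it, and the
#'   first b resamples do not change when B grows.
#' @param ties Tie handling.
#' @return Object of class `model_inclusion`: data frame (factor,
#'   included, inclusion_percent) with attributes `B`, `B_used`,
#'   `failures`, `seed`.
#' @export
bootstrap_model_inclusion <- function(coded, candidates = score_factor_names(),
                                      B = 1000, p_enter = 0.05, p_stay = 0.05,
                                      seed = 1L, ties = "breslow") {
  stopifnot(B >= 1)
  sub <- complete_for(coded, candidates)
  n <- nrow(sub)
  seeds <- substream_seeds(seed, B)
  count <- stats::setNames(integer(length(candidates)), candidates)
  skipped <- stats::setNames(integer(length(candidates)), candidates)
  failures <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      stepwise_cox(sub[idx, , drop = FALSE], candidates,
                   p_enter = p_enter, p_stay = p_stay, ties = ties),
      error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    count[res$selected] <- count[res$selected] + 1L
    skipped[res$skipped] <- skipped[res$skipped] + 1L
  }
  used <- B - failures
  out <- data.frame(
    factor = candidates,
    included = unname(count),
    inclusion_percent = unname(100 * count / max(used, 1)),
    skipped_resamples = unname(skipped),
    stringsAsFactors = FALSE)
  structure(out, class = c("model_inclusion", "data.frame"),
            B = B, B_used = used, failures = failures, seed = seed)
}

#' Bootstrap stability of per-level 5-year survival rates
#'
#' For each of `B` resamples (with replacement, original size) and each
#' level of each scored factor, computes the 5-year Kaplan-Meier rate;
#' summarizes median, min, max, mean and SD across resamples next to
#' the original-sample rate. Levels empty in a resample contribute no
#' value for that resample (count reported).
#'
#' @param coded Coded cohort with `time`/`event`.
#' @param score_factors Factors to summarize.
#' @param B Number of resamples.
#' @param seed Root seed (same substream contract as
#'   [bootstrap_model_inclusion()]).
#' @param horizon Rate horizon in years.
#' @return Object of class `rate_bootstrap`: data frame (factor, level,
#'   median, min, max, mean, sd, original, n_missing) with attributes
#'   `B` and `seed`.
#' @export
bootstrap_level_rates <- function(coded, score_factors = score_factor_names(),
                                  B = 1000, seed = 1L, horizon = 5) {
  stopifnot(B >= 1)
  lv <- score_factor_levels()
  keys <- unlist(lapply(score_factors, function(f) paste(f, lv[[f]], sep = ":")))
  n <- nrow(coded)
  seeds <- substream_seeds(seed, B)
  rates <- matrix(NA_real_, nrow = B, ncol = length(keys),
                  dimnames = list(NULL, keys))
  level_rate <- function(dat, f, l) {
    sel <- !is.na(dat[[f]]) & dat[[f]] == l
    if (!any(sel)) return(NA_real_)
    suppressWarnings(rate_at(km_fit(dat$time[sel], dat$event[sel]), horizon)$rate)
  }
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    dat <- coded[sample.int(n, n, replace = TRUE), , drop = FALSE]
    k <- 0
    for (f in score_factors) for (l in lv[[f]]) {
      k <- k + 1
      rates[b, k] <- level_rate(dat, f, l)
    }
  }
  rows <- list()
  k <- 0
  for (f in score_factors) for (l in lv[[f]]) {
    k <- k + 1
    x <- rates[, k]
    ok <- x[!is.na(x)]
    rows[[keys[k]]] <- data.frame(
      factor = f, level = l,
      median = if (length(ok)) stats::median(ok) else NA_real_,
      min = if (length(ok)) min(ok) else NA_real_,
      max = if (length(ok)) max(ok) else NA_real_,
      mean = if (length(ok)) mean(ok) else NA_real_,
      sd = if (length(ok) > 1) stats::sd(ok) else 0,
      original = level_rate(coded, f, l),
      n_missing = sum(is.na(x)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rate_bootstrap", "data.frame"),
            B = B, seed = seed)
}

#' Precision of the original-sample 5-year rate estimates
#'
#' Half-width of the 95% Greenwood confidence interval of the 5-year
#' survival rate for each factor level of the original cohort -- a
#' direct report of how precisely the cohort pins down each rate.
#'
#' @inheritParams bootstrap_level_rates
#' @return Data frame (factor, level, rate, ci_half_width in percent).
#' @export
rate_precision_report <- function(coded, score_factors = score_factor_names(),
                                  horizon = 5) {
  lv <- score_factor_levels()
  rows <- list()
  for (f in score_factors) for (l in lv[[f]]) {
    sel <- !is.na(coded[[f]]) & coded[[f]] == l
    if (!any(sel)) next
    r <- suppressWarnings(
      rate_at(km_fit(coded$time[sel], coded$event[sel]), horizon))
    rows[[paste(f, l)]] <- data.frame(
      factor = f, level = l, rate = r$rate,
      ci_half_width = (r$upper - r$lower) / 2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
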