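#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function with Greenwood
#' variance. Subjects censored at an event time remain in the risk set
#' for the events at that time (the usual censored-after-event tie
#' rule); the curve is right-continuous.
#'
#' @param time Strictly positive follow-up times (years).
#' @param event Logical (or 0/1) event indicator; `TRUE` = death.
#' @return Object of class `km_curve`: data frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `survival`,
#'   `greenwood_var`), with attributes `n`, `n_events` and `max_time`
#'   (largest observed time, event or censored).
#' @export
#' @examples
#' km_fit(c(1, 2, 2, 3, 4), c(FALSE, TRUE, TRUE, FALSE, TRUE))
km_fit <- function(time, event) {
  if (length(time) == 0) stop_lungscore("empty sample", "lungscore_empty_sample")
  stopifnot(length(time) == length(event))
  if (any(is.na(time)) || any(is.na(event))) stop("missing time/event values")
  if (any(time <= 0)) stop("times must be strictly positive")
  event <- as.logical(event)

  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  if (!any(event)) {
    curve <- data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), survival = numeric(0),
                        greenwood_var = numeric(0))
  } else {
    # one pass over distinct times: risk set at t = subjects with time >= t
    tf <- factor(time, levels = unique(time))
    cnt <- tabulate(tf)
    dts <- vapply(split(as.numeric(event), tf), sum, numeric(1))
    risk <- n - c(0, cumsum(cnt))[seq_along(cnt)]
    has_event <- dts > 0
    ut <- unique(time)[has_event]
    n_risk <- risk[has_event]
    n_event <- dts[has_event]
    surv <- cumprod(1 - n_event / n_risk)
    gterm <- n_event / (n_risk * (n_risk - n_event))  # Inf when S drops to 0
    gvar <- surv^2 * cumsum(gterm)
    gvar[surv == 0] <- 0
    curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                        survival = surv, greenwood_var = gvar)
  }
  structure(curve, class = c("km_curve", "data.frame"),
            n = n, n_events = sum(event), max_time = max(time))
}

#' Survival rate (percent) at a time point, with Greenwood 95% CI
#'
#' Evaluates the step function at the latest event time at or before
#' `t`, scaled to percent. The confidence interval is a plain-scale
#' normal interval from the Greenwood variance, clipped to
#' \\[0, 100\\]; a log-log transformed interval is available via
#' `transform = "loglog"`.
#'
#' @param curve A `km_curve`.
#' @param t Time point (years), `t >= 0`.
#' @param conf Confidence level (default 0.95).
#' @param transform `"plain"` (default, clipped) or `"loglog"`.
#' @return List with `rate`, `lower`, `upper` (percent) and
#'   `extrapolated` (`TRUE` with a warning when `t` lies beyond the
#'   largest observed time).
#' @export
rate_at <- function(curve, t, conf = 0.95, transform = c("plain", "loglog")) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  transform <- match.arg(transform)
  extrapolated <- t > attr(curve, "max_time")
  if (extrapolated)
    warning("time ", t, " is beyond the last observed time ",
            attr(curve, "max_time"), "; returning the last estimate")
  idx <- which(curve$time <= t)
  if (length(idx) == 0) {
    return(list(rate = 100, lower = 100, upper = 100,
                extrapolated = extrapolated))
  }
  i <- max(idx)
  s <- curve$survival[i]; v <- curve$greenwood_var[i]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (transform == "plain" || s %in% c(0, 1) || v == 0) {
    lo <- max(0, s - z * sqrt(v)); hi <- min(1, s + z * sqrt(v))
  } else {
    # CI on log(-log S), always inside (0, 1)
    se_ll <- sqrt(v) / (s * abs(log(s)))
    lo <- s^exp(z * se_ll); hi <- s^exp(-z * se_ll)
  }
  list(rate = 100 * s, lower = 100 * lo, upper = 100 * hi,
       extrapolated = extrapolated)
}

#' Median survival time with confidence interval
#'
#' The smallest event time at which the survival estimate drops to 0.5
#' or below; `NA` ("not attained") when the curve never does. The CI
#' bounds are the first crossing times of the pointwise Greenwood
#' confidence limits, in the style of Brookmeyer-Crowley.
#'
#' @param curve A `km_curve`.
#' @param conf Confidence level.
#' @return List with `median`, `lower`, `upper` (years; `NA` when not
#'   attained).
#' @export
km_median <- function(curve, conf = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(curve$greenwood_var)
  first_cross <- function(vals) {
    i <- which(vals <= 0.5)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  list(median = first_cross(curve$survival),
       lower = first_cross(curve$survival - z * se),
       upper = first_cross(curve$survival + z * se))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, %d distinct event times\n",
              attr(x, "n"), attr(x, "n_events"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
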