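#' k-group log-rank test
#'
#' Observed-minus-expected log-rank chi-square over the pooled event
#' times, with the hypergeometric variance-covariance at each event
#' time, on k - 1 degrees of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators (logical or 0/1).
#' @param group Group labels; at least two nonempty groups.
#' @return Object of class `log_rank`: list with `chi_square`, `df`,
#'   `p_value`, and the per-group `observed` and `expected` event
#'   counts.
#' @export
logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  event <- as.logical(event)
  if (!is.factor(group)) group <- factor(group)  # keep declared levels
  k <- nlevels(group)
  if (k < 2) stop_lungscore(">=2 nonempty groups required",
                            "lungscore_too_few_groups")
  if (any(table(group) == 0))
    stop_lungscore("empty group in log-rank comparison",
                   "lungscore_empty_group")
  ut <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(levels(group), function(g) sum(time == t & event & group == g),
                  numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + c_t * (diag(n_g / n_t, k) - tcrossprod(n_g / n_t))
    }
  }
  u <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(t(u) %*% solve(Vsub, u)), error = function(e) 0)
  structure(list(chi_square = chi, df = k - 1,
                 p_value = stats::pchisq(chi, k - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "log_rank")
}

#' @export
print.log_rank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
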