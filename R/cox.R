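#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the log partial likelihood over the supplied design matrix
#' with Breslow (default) or Efron handling of tied event times.
#' Iteration starts at zero coefficients and uses Newton steps with
#' step-halving, stopping when the maximum absolute score component
#' falls below `tol`. The global score test is evaluated at the zero
#' coefficient vector.
#'
#' @param X Numeric design matrix with named columns; no constant
#'   column, complete cases only.
#' @param time Strictly positive follow-up times.
#' @param event Event indicator (logical or 0/1).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: coefficients, variance matrix,
#'   hazard ratios with 95% Wald CIs (z = 1.959964), per-term two-sided
#'   Wald p-values, the global score test at beta = 0, log partial
#'   likelihoods at zero and at the optimum, and iteration count.
#' @export
cox_fit <- function(X, time, event, ties = c("breslow", "efron"),
                    tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  event <- as.logical(event)
  stopifnot(nrow(X) == length(time), length(time) == length(event))
  if (any(is.na(X)) || any(is.na(time)) || any(is.na(event)))
    stop("cox_fit requires complete cases")
  if (any(apply(X, 2, function(col) length(unique(col)) == 1)))
    stop("constant column in design matrix: ",
         paste(colnames(X)[apply(X, 2, function(col) length(unique(col)) == 1)],
               collapse = ", "))

  o <- order(time)
  Xs <- X[o, , drop = FALSE]; ts <- time[o]; ev <- as.integer(event[o])
  p <- ncol(X)
  deriv <- function(beta) cox_deriv_cpp(Xs, ts, ev, beta, ties == "efron")

  beta <- rep(0, p)
  d <- deriv(beta)
  d0 <- d                                  # derivatives at beta = 0
  trace <- numeric(0)
  iter <- 0
  converged <- max(abs(d$score)) < tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(d$info, d$score), error = function(e)
      stop_lungscore("singular information matrix in Newton step",
                     "lungscore_singular_information"))
    # step-halving: insist on non-decreasing partial likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      dc <- deriv(cand)
      # tolerate float-level decreases (loglik magnitudes grow with n)
      if (dc$loglik >= d$loglik - 1e-9 * (abs(d$loglik) + 1) ||
          lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand; d <- dc
    trace <- c(trace, d$loglik)
    if (any(abs(beta) > 15))
      stop_lungscore(
        "monotone partial likelihood (perfect separation suspected)",
        "lungscore_monotone_likelihood", beta = beta)
    converged <- max(abs(d$score)) < tol
  }
  if (!converged)
    stop_lungscore(
      paste0("Newton iteration failed to converge in ", max_iter,
             " iterations"),
      "lungscore_nonconvergence", trace = trace)

  V <- solve(d$info)
  se <- sqrt(diag(V))
  z975 <- 1.959964
  coef <- drop(beta); names(coef) <- colnames(X)
  zval <- coef / se
  score_chisq <- drop(t(d0$score) %*% solve(d0$info, d0$score))
  structure(list(
    coef = coef,
    se = stats::setNames(se, colnames(X)),
    var = V,
    hr = exp(coef),
    ci95 = cbind(lower = exp(coef - z975 * se), upper = exp(coef + z975 * se)),
    wald_p = 2 * stats::pnorm(-abs(zval)),
    score_chisq = score_chisq,
    score_df = p,
    score_p = stats::pchisq(score_chisq, p, lower.tail = FALSE),
    loglik = c(null = d0$loglik, final = d$loglik),
    ties = ties, n = nrow(X), n_events = sum(event), iter = iter
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(coef = x$coef, HR = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    p = x$wald_p)
  print(round(tab, 4))
  cat(sprintf("Global score test: chi-square = %.4f on %d df, p = %.4g\n",
              x$score_chisq, x$score_df, x$score_p))
  invisible(x)
}

# Partial log-likelihood at an arbitrary beta (used by oracle tests and
# the stepwise score test).
cox_loglik <- function(X, time, event, beta, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  o <- order(time)
  cox_deriv_cpp(X[o, , drop = FALSE], time[o], as.integer(as.logical(event))[o],
                beta, ties == "efron")$loglik
}

# Block score test for adding the columns of Xadd to a model already
# fitted on Xbase (coefficients beta_base). Returns the chi-square,
# df and p-value of the partitioned score test evaluated at
# (beta_base, 0).
cox_score_test_add <- function(Xbase, beta_base, Xadd, time, event,
                               ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  Xadd <- as.matrix(Xadd)
  q <- ncol(Xadd)
  if (is.null(Xbase) || ncol(as.matrix(Xbase)) == 0) {
    Xf <- Xadd; beta <- rep(0, q); idx <- seq_len(q)
  } else {
    Xbase <- as.matrix(Xbase)
    Xf <- cbind(Xbase, Xadd)
    beta <- c(beta_base, rep(0, q))
    idx <- ncol(Xbase) + seq_len(q)
  }
  o <- order(time)
  d <- cox_deriv_cpp(Xf[o, , drop = FALSE], time[o],
                     as.integer(as.logical(event))[o], beta, ties == "efron")
  U2 <- d$score[idx]
  I <- d$info
  if (length(idx) == ncol(Xf)) {
    Vcond <- I
  } else {
    I11 <- I[-idx, -idx, drop = FALSE]
    I12 <- I[-idx, idx, drop = FALSE]
    I22 <- I[idx, idx, drop = FALSE]
    Vcond <- I22 - crossprod(I12, solve(I11, I12))
  }
  chi <- tryCatch(drop(t(U2) %*% solve(Vcond, U2)), error = function(e) NA_real_)
  list(chi_square = chi, df = q,
       p_value = stats::pchisq(chi, q, lower.tail = FALSE))
}
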