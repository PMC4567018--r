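# Build a treatment-contrast design matrix from a coded cohort for the
# requested factors. Factor columns use the published reference levels;
# "tumor_size" enters as the continuous diameter. Returns the matrix
# with an "assign" attribute mapping columns to factors and a "terms"
# attribute with display labels.
build_design <- function(coded, factors) {
  lv <- score_factor_levels()
  ref <- score_factor_reference()
  cols <- list(); assign <- character(0); labels <- character(0)
  for (f in factors) {
    if (f == "tumor_size") {
      cols[[f]] <- matrix(coded$tumor_size, ncol = 1,
                          dimnames = list(NULL, "tumor_size"))
      assign <- c(assign, f)
      labels <- c(labels, "Tumor diameter (cm)")
      next
    }
    if (f %in% names(lv)) {
      f_levels <- lv[[f]]; f_ref <- ref[[f]]
    } else if (f %in% names(coded)) {
      # ad-hoc factor column (e.g. an external covariate): first
      # observed level is the reference
      f_levels <- if (is.factor(coded[[f]])) levels(coded[[f]])
                  else sort(unique(as.character(coded[[f]])))
      f_ref <- f_levels[1]
    } else stop("unknown factor: ", f)
    x <- factor(coded[[f]], levels = c(f_ref, setdiff(f_levels, f_ref)))
    non_ref <- levels(x)[-1]
    m <- vapply(non_ref, function(l) as.numeric(x == l),
                numeric(length(x)))
    m <- matrix(m, ncol = length(non_ref),
                dimnames = list(NULL, paste0(f, "=", non_ref)))
    cols[[f]] <- m
    assign <- c(assign, rep(f, length(non_ref)))
    labels <- c(labels, paste0(non_ref, " (vs ", f_ref, ")"))
  }
  X <- do.call(cbind, cols)
  attr(X, "assign") <- assign
  attr(X, "labels") <- labels
  X
}

# Complete-case restriction for a set of factors; returns the coded
# rows with no missing value in any requested factor (or tumor_size).
complete_for <- function(coded, factors) {
  need <- unique(c(factors, "time", "event"))
  need <- intersect(need, names(coded))
  keep <- stats::complete.cases(coded[, need, drop = FALSE])
  coded[keep, , drop = FALSE]
}

#' Univariate Cox screen over prognostic factors
#'
#' Fits one single-factor Cox model per factor (complete cases for that
#' factor), reporting per-level hazard ratios against the published
#' reference levels, Wald p-values, and the global score-test p-value of
#' each single-factor model. Factors with a single observed level are
#' skipped with a warning.
#'
#' @param coded Coded cohort from [code_factors()] (needs `time` and
#'   `event` columns).
#' @param factors Factor columns to screen; defaults to the eight
#'   scored factors plus continuous `tumor_size`.
#' @param ties Tie handling passed to [cox_fit()].
#' @return Object of class `uv_screen`: data frame with one row per
#'   non-reference level (factor, term, n, events, hr, ci, wald_p,
#'   score_p).
#' @export
univariate_screen <- function(coded,
                              factors = c(score_factor_names(), "tumor_size"),
                              ties = "breslow") {
  rows <- list()
  for (f in factors) {
    sub <- complete_for(coded, f)
    lvls_seen <- if (f == "tumor_size") length(unique(sub$tumor_size))
                 else length(unique(as.character(sub[[f]])))
    if (lvls_seen < 2) {
      warning("factor ", f, " has a single observed level; skipped")
      next
    }
    X <- build_design(sub, f)
    fit <- cox_fit(X, sub$time, sub$event, ties = ties)
    if (f == "tumor_size") {
      level_n <- nrow(sub); level_events <- sum(sub$event)
    } else {
      non_ref <- sub(paste0(f, "="), "", colnames(X), fixed = TRUE)
      level_n <- vapply(non_ref, function(l) sum(sub[[f]] == l), numeric(1))
      level_events <- vapply(non_ref, function(l)
        sum(sub$event[sub[[f]] == l]), numeric(1))
    }
    rows[[f]] <- data.frame(
      factor = f,
      term = attr(X, "labels"),
      n = nrow(sub), events = sum(sub$event),
      level_n = unname(level_n), level_events = unname(level_events),
      coef = unname(fit$coef),
      hr = unname(fit$hr),
      hr_lower = unname(fit$ci95[, "lower"]),
      hr_upper = unname(fit$ci95[, "upper"]),
      wald_p = unname(fit$wald_p),
      score_p = fit$score_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("uv_screen", "data.frame"))
}

# Multi-degree-of-freedom Wald test for each factor block of a fitted
# joint model.
factor_wald_tests <- function(fit, assign) {
  out <- list()
  for (f in unique(assign)) {
    idx <- which(assign == f)
    b <- fit$coef[idx]
    Vb <- fit$var[idx, idx, drop = FALSE]
    chi <- drop(t(b) %*% solve(Vb, b))
    out[[f]] <- data.frame(factor = f, df = length(idx), chi_square = chi,
                           p = stats::pchisq(chi, length(idx), lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multivariate Cox fit over the scored factors
#'
#' Single joint proportional-hazards fit of the eight scored factors
#' (complete cases across all of them), with per-term hazard ratios,
#' CIs and Wald p-values plus a multi-degree-of-freedom Wald test per
#' factor block.
#'
#' @inheritParams univariate_screen
#' @param factors Factor columns for the joint model (default: the
#'   eight scored factors).
#' @return A `cox_fit` with extra components `terms` (data frame of
#'   per-term results), `factor_tests` (per-factor Wald tests) and
#'   `n_complete`.
#' @export
multivariate_fit <- function(coded, factors = score_factor_names(),
                             ties = "breslow") {
  sub <- complete_for(coded, factors)
  X <- build_design(sub, factors)
  fit <- cox_fit(X, sub$time, sub$event, ties = ties)
  assign <- attr(X, "assign")
  fit$terms <- data.frame(
    factor = assign, term = attr(X, "labels"),
    coef = unname(fit$coef), hr = unname(fit$hr),
    hr_lower = unname(fit$ci95[, "lower"]),
    hr_upper = unname(fit$ci95[, "upper"]),
    wald_p = unname(fit$wald_p), stringsAsFactors = FALSE)
  fit$factor_tests <- factor_wald_tests(fit, assign)
  fit$n_complete <- nrow(sub)
  fit
}

#' Stepwise Cox model selection
#'
#' Classical forward stepwise selection with backward checks: at each
#' forward step the candidate factor (entered as a block of level
#' contrasts) with the smallest block score-test p-value below
#' `p_enter` enters (ties broken by smaller p, then declaration order);
#' after each entry, any included factor whose multi-df Wald p-value
#' exceeds `p_stay` is removed (worst first). A removed factor is
#' barred from re-entry, which guarantees termination when the entry
#' (score) and stay (Wald) tests disagree at the threshold.
#' Deterministic for a given input.
#'
#' @inheritParams univariate_screen
#' @param candidates Candidate factor columns.
#' @param p_enter Score-test p-value required to enter (default 0.05).
#' @param p_stay Wald p-value required to stay (default 0.05).
#' @return List with `selected` (character vector, possibly empty),
#'   `fit` (the final `cox_fit`, or `NULL` for the empty model) and
#'   `trace` (data frame of entry/removal steps).
#' @export
stepwise_cox <- function(coded, candidates = score_factor_names(),
                         p_enter = 0.05, p_stay = 0.05, ties = "breslow") {
  stopifnot(p_enter <= p_stay)
  sub <- complete_for(coded, candidates)
  # candidates with a single observed level cannot be entered
  usable <- candidates[vapply(candidates, function(f) {
    v <- if (f == "tumor_size") sub$tumor_size else as.character(sub[[f]])
    length(unique(v)) >= 2
  }, logical(1))]
  dropped <- setdiff(candidates, usable)

  selected <- character(0)
  banned <- character(0)   # removed factors may not re-enter (termination)
  fit <- NULL
  trace <- list()
  note <- function(action, factor, p)
    trace[[length(trace) + 1]] <<- data.frame(
      action = action, factor = factor, p = p, stringsAsFactors = FALSE)

  repeat {
    changed <- FALSE
    ## forward step: block score test for each remaining candidate
    remaining <- setdiff(usable, c(selected, banned))
    if (length(remaining)) {
      Xbase <- if (length(selected)) build_design(sub, selected) else NULL
      beta_base <- if (length(selected)) fit$coef else numeric(0)
      pvals <- vapply(remaining, function(f) {
        Xadd <- build_design(sub, f)
        st <- cox_score_test_add(Xbase, beta_base, Xadd, sub$time, sub$event,
                                 ties = ties)
        st$p_value
      }, numeric(1))
      if (any(!is.na(pvals) & pvals < p_enter)) {
        best <- remaining[which.min(pvals)]   # ties: lowest p then order
        selected <- c(selected, best)
        X <- build_design(sub, selected)
        fit <- cox_fit(X, sub$time, sub$event, ties = ties)
        note("enter", best, min(pvals, na.rm = TRUE))
        changed <- TRUE
      }
    }
    ## backward step: drop any factor whose block Wald p exceeds p_stay
    repeat {
      if (length(selected) == 0) break
      X <- build_design(sub, selected)
      fit <- cox_fit(X, sub$time, sub$event, ties = ties)
      ft <- factor_wald_tests(fit, attr(X, "assign"))
      if (all(ft$p <= p_stay)) break
      worst <- ft$factor[which.max(ft$p)]
      selected <- setdiff(selected, worst)
      banned <- c(banned, worst)
      note("remove", worst, max(ft$p))
      changed <- TRUE
      if (length(selected) == 0) { fit <- NULL; break }
    }
    if (!changed) break
  }
  list(selected = selected, fit = fit,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(action = character(0), factor = character(0),
                               p = numeric(0)),
       skipped = dropped)
}

#' Export a univariate screen or multivariate fit as a CSV table
#' @param x A `uv_screen` or the result of [multivariate_fit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cox_table <- function(x, path) {
  tab <- if (inherits(x, "uv_screen")) as.data.frame(x) else x$terms
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
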