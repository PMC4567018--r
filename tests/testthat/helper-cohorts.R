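# Shared fixtures, all generated in code.

# Coded synthetic cohort at the default study conditions.
sim_coded <- function(n, seed, ...) {
  code_factors(generate_cohort(cohort_sim_config(n = n, seed = seed, ...))$cohort)
}

# Small random censored sample (tie-free unless rounded by the caller).
rand_surv <- function(n, seed, event_p = 0.6, round_to = NULL) {
  set.seed(seed)
  tm <- rexp(n)
  if (!is.null(round_to)) tm <- round(tm, round_to) + 10^(-round_to)
  list(time = tm, event = runif(n) < event_p)
}

# A valid three-row patient table for I/O tests.
tiny_patients <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    age = c(55, 72, 81),
    sex = c("female", "male", "male"),
    qol = c(80, 50, 30),
    ecog = c(0, 2, NA),
    smoking_cessation = c("quit", "quit", "kept_smoking"),
    tumor_size = c(1.5, 2.0, 4.2),
    nodal = c("none", "ipsi_hilar", "contralateral_mediastinal"),
    mets = c("absent", "absent", "present"),
    time = c(6.2, 1.4, 0.5),
    event = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

write_tiny_csv <- function(df = tiny_patients(), path = tempfile(fileext = ".csv")) {
  write_cohort_csv(df, path)
  path
}

# Brute-force product-limit oracle: direct product over risk sets.
km_oracle <- function(time, event, at) {
  ut <- sort(unique(time[event]))
  s <- 1
  for (t in ut[ut <= at]) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event)
    s <- s * (1 - d_t / n_t)
  }
  s
}

# Grid-search oracle for a single-covariate Cox partial likelihood.
cox_grid_oracle <- function(x, time, event, ties = "breslow",
                            lo = -5, hi = 5, step = 1e-4) {
  X <- matrix(x, ncol = 1)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(b)
    lungscore:::cox_loglik(X, time, event, b, ties = ties), numeric(1))
  grid[which.max(ll)]
}
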