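test_that("a well-formed file round-trips with no rejects", {
  path <- write_tiny_csv()
  ch <- read_cohort(path)
  expect_s3_class(ch, "lung_cohort")
  expect_equal(nrow(ch$patients), 3)
  expect_equal(nrow(ch$rejects), 0)
  expect_equal(unname(ch$missing["ecog"]), 1L)
})

test_that("invariant violations reject rows with reasons", {
  df <- tiny_patients()
  df$qol[1] <- 150                         # out of range
  df$time[2] <- -1                         # non-positive follow-up
  df <- rbind(df, within(df[3, ], nodal <- "everywhere"))
  path <- write_tiny_csv(df)
  ch <- read_cohort(path)
  expect_equal(nrow(ch$patients), 1)
  expect_equal(nrow(ch$rejects), 3)
  expect_true(any(grepl("qol out of range", ch$rejects$reason)))
  expect_true(any(grepl("time", ch$rejects$reason)))
  expect_true(any(grepl("nodal", ch$rejects$reason)))
})

test_that("a missing required column is a hard failure naming the column", {
  df <- tiny_patients()
  df$nodal <- NULL
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "nodal",
               class = "lungscore_missing_column")
})

test_that("column mapping adapts external headers", {
  df <- tiny_patients()
  names(df)[names(df) == "qol"] <- "overall_qol"
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  ch <- read_cohort(path, cohort_columns(qol = "overall_qol"))
  expect_equal(ch$patients$qol, tiny_patients()$qol)
})

test_that("factor coding follows the published boundary conventions", {
  base <- tiny_patients()[1, ]
  probe <- function(field, value) {
    base[[field]] <- value
    code_factors(base)
  }
  # QOL deficit threshold is inclusive at 50
  expect_equal(as.character(probe("qol", 50)$qol_level), "deficit")
  expect_equal(as.character(probe("qol", 51)$qol_level), "nondeficit")
  # tumor size threshold inclusive at 2 cm
  expect_equal(as.character(probe("tumor_size", 2.0)$size_level), "le2cm")
  expect_equal(as.character(probe("tumor_size", 2.01)$size_level), "gt2cm")
  # age bins left-closed / right-open
  expect_equal(as.character(probe("age", 59.999)$age_level), "lt60")
  expect_equal(as.character(probe("age", 60)$age_level), "60to70")
  expect_equal(as.character(probe("age", 80)$age_level), "ge80")
  # ECOG 0-1 vs 2-4, missing propagates
  expect_equal(as.character(probe("ecog", 1)$ecog_level), "ps01")
  expect_equal(as.character(probe("ecog", 2)$ecog_level), "ps234")
  expect_true(is.na(probe("ecog", NA)$ecog_level))
})

test_that("coding is idempotent through a write/read round-trip", {
  g <- generate_cohort(cohort_sim_config(n = 60, seed = 11))
  coded1 <- code_factors(g$cohort)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(g$cohort, path)
  coded2 <- code_factors(read_cohort(path))
  for (f in score_factor_names())
    expect_equal(as.character(coded1[[f]]), as.character(coded2[[f]]))
  expect_equal(coded1$time, coded2$time)
  expect_equal(coded1$event, coded2$event)
})

test_that("demographic summaries count levels and percentages correctly", {
  df <- tiny_patients()                     # 1 female, 2 male
  df <- rbind(df, within(df[1, ], patient_id <- "p4"))   # 2 female, 2 male
  s <- summarize_demographics(df)
  fem <- s$categorical[s$categorical$variable == "Sex" &
                       s$categorical$level == "female", ]
  expect_equal(fem$n, 2L)
  expect_equal(fem$percent, 50.0)
  # percentages sum to 100 within each variable over non-missing values
  sums <- tapply(s$categorical$percent, s$categorical$variable, sum)
  expect_true(all(abs(sums - 100) <= 0.1))
  # tumor-size moments
  df2 <- tiny_patients()
  df2$tumor_size <- c(1, 2, 3)
  df2 <- rbind(df2, within(df2[1, ], tumor_size <- 4))
  s2 <- summarize_demographics(df2)
  expect_equal(s2$tumor_size$mean, 2.5)
  expect_equal(s2$tumor_size$median, 2.5)
  expect_error(summarize_demographics(tiny_patients()[0, ]),
               class = "lungscore_empty_cohort")
})

test_that("generated cohorts reproduce the configured marginals", {
  g <- generate_cohort(cohort_sim_config(n = 5000, seed = 5))
  coded <- code_factors(g$cohort)
  marg <- default_marginals()
  for (f in score_factor_names()) {
    freq <- prop.table(table(coded[[f]]))
    expect_true(all(abs(freq[names(marg[[f]])] - marg[[f]]) < 0.02),
                label = paste("marginals recovered for", f))
  }
})
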