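test_that("the level-score rule reproduces every published rate/score pair", {
  # worked examples of the rule
  expect_identical(level_score(62), 6L)
  expect_identical(level_score(24), 2L)
  # reconciliation cases: rates are rounded to whole percent first
  expect_identical(level_score(64.8), 7L)   # 65 -> 6.5 -> 7
  expect_identical(level_score(58.6), 6L)   # 59 -> 5.9 -> 6
  # endpoints
  expect_identical(level_score(0), 0L)
  expect_identical(level_score(100), 10L)
  # every row of the packaged reference table
  ref <- reference_score_table()
  expect_identical(level_score(ref$five_year_rate), as.integer(ref$score))
  # out-of-range rates are rejected
  expect_error(level_score(101), class = "lungscore_bad_rate")
  expect_error(level_score(-1), class = "lungscore_bad_rate")
  # alternative policies disagree exactly where documented
  expect_identical(level_score(64.8, policy = "round_once"), 6L)
  expect_identical(level_score(65, policy = "floor"), 6L)
})

test_that("total scores span 24 to 52 under the reference table", {
  ref <- reference_score_table()
  lv <- score_factor_levels()
  best <- data.frame(qol_level = "nondeficit", age_level = "lt60",
                     sex_level = "female", ecog_level = "ps01",
                     smoking_level = "quit", size_level = "le2cm",
                     nodal_level = "none", mets_level = "absent",
                     stringsAsFactors = FALSE)
  expect_identical(total_score(best, ref), 52L)
  worst <- data.frame(qol_level = "deficit", age_level = "ge80",
                      sex_level = "male", ecog_level = "ps234",
                      smoking_level = "kept_smoking", size_level = "gt2cm",
                      nodal_level = "contralateral_mediastinal",
                      mets_level = "present", stringsAsFactors = FALSE)
  expect_identical(total_score(worst, ref), 24L)
  # per-factor maxima sum to the best profile's total
  expect_identical(sum(tapply(ref$score, ref$factor, max)), 52L)
  # male instead of female costs exactly the female/male score gap
  male_best <- within(best, sex_level <- "male")
  expect_identical(total_score(male_best, ref), 52L - (7L - 5L))
  # missing a scored factor cannot be silently scored
  incomplete <- within(best, ecog_level <- NA_character_)
  expect_error(total_score(incomplete, ref),
               class = "lungscore_incomplete_for_scoring")
  expect_true(is.na(total_score(incomplete, ref, on_incomplete = "na")))
})

test_that("score-table additivity: shifting one factor shifts every total", {
  coded <- sim_coded(400, seed = 31)
  ref <- reference_score_table()
  t1 <- total_score(coded, ref, on_incomplete = "na")
  shifted <- ref
  shifted$score[shifted$factor == "qol_level"] <-
    shifted$score[shifted$factor == "qol_level"] + 3L
  t2 <- total_score(coded, shifted, on_incomplete = "na")
  expect_equal(t2, t1 + 3L)
})

test_that("category bins follow the published headline scheme", {
  s4 <- category_scheme("category4")
  expect_equal(s4$label, c("32-37", "38-43", "44-47", "48-49", "50-52"))
  expect_equal(as.character(categorize(39, s4)), "38-43")
  expect_equal(as.character(categorize(37, s4)), "32-37")  # inclusive upper
  expect_equal(as.character(categorize(38, s4)), "38-43")
  expect_equal(as.character(categorize(52, s4)), "50-52")
  expect_error(categorize(31, s4), class = "lungscore_score_out_of_range")
  expect_error(categorize(53, s4), class = "lungscore_score_out_of_range")
  # all four published schemes load and tile their ranges
  for (nm in paste0("category", 1:4)) {
    s <- category_scheme(nm)
    expect_equal(s$lo[1], 32)
    expect_equal(s$hi[nrow(s)], 52)
  }
})

test_that("built score tables are monotone when effects are strongly separated", {
  coded <- sim_coded(5000, seed = 32)
  tab <- build_score_table(coded)
  lv <- score_factor_levels()
  # generator level order is best-to-worst within each factor except the
  # coding-order factors where the reference (worst) level comes last
  ordered_best_first <- list(
    qol_level = c("nondeficit", "deficit"),
    age_level = c("lt60", "60to70", "70to80", "ge80"),
    sex_level = c("female", "male"),
    ecog_level = c("ps01", "ps234"),
    smoking_level = c("quit", "kept_smoking"),
    size_level = c("le2cm", "gt2cm"),
    nodal_level = c("none", "ipsi_hilar", "ipsi_mediastinal",
                    "contralateral_mediastinal"),
    mets_level = c("absent", "present"))
  for (f in names(ordered_best_first)) {
    sc <- tab$score[match(paste(f, ordered_best_first[[f]]),
                          paste(tab$factor, tab$level))]
    expect_true(all(diff(sc) <= 0),
                label = paste("scores non-increasing best-to-worst for", f))
  }
})

test_that("degenerate levels score zero and empty levels are an error", {
  coded <- sim_coded(200, seed = 33)
  # all deficit patients die in year one: that level scores 0
  sel <- coded$qol_level == "deficit"
  coded$time[sel] <- runif(sum(sel), 0.1, 0.9)
  coded$event[sel] <- TRUE
  tab <- build_score_table(coded, "qol_level")
  expect_identical(tab$score[tab$level == "deficit"], 0L)
  coded2 <- coded[coded$mets_level == "absent", ]
  expect_error(build_score_table(coded2, "mets_level"),
               class = "lungscore_empty_level")
})

test_that("the per-total-score report partitions the scored cohort", {
  coded <- sim_coded(600, seed = 34)
  scored <- coded[stats::complete.cases(coded[score_factor_names()]), ]
  totals <- total_score(scored, reference_score_table())
  rep_ <- per_total_score_report(totals, scored$time, scored$event)
  expect_equal(sum(rep_$n), nrow(scored))
  expect_true(all(rep_$total_score %in% sort(unique(totals))))
  # a subgroup whose curve never reaches 0.5 reports NA ("not attained")
  high <- rep_[rep_$five_year_rate > 60, ]
  if (nrow(high)) expect_true(any(is.na(high$median_years)))
  # single-patient subgroup with an early event has that median
  r1 <- per_total_score_report(5L, 0.48, TRUE)
  expect_equal(r1$median_years, 0.48)
})

test_that("category report recovers a rate ratio of 3 between two bins", {
  set.seed(35)
  n <- 1500
  bin_of <- rep(c(40, 50), each = n / 2)      # two occupied category-4 bins
  tm <- rexp(n, ifelse(bin_of == 40, 0.45, 0.15))
  cens <- runif(n, 0, 12)
  rep_ <- category_report(bin_of, pmin(tm, cens), tm <= cens,
                          category_scheme("category4"))
  hr <- rep_$hr[rep_$bin == "38-43"]
  expect_gt(hr, 2.4); expect_lt(hr, 3.7)
  expect_lt(attr(rep_, "logrank")$p_value, 1e-10)
  expect_error(category_report(rep(40, 10), rexp(10), rep(TRUE, 10),
                               category_scheme("category4")),
               class = "lungscore_too_few_bins")
})

test_that("category ordering holds on scored synthetic cohorts", {
  ok <- vapply(1:10, function(s) {
    coded <- sim_coded(2000, seed = 9000 + s)
    scored <- coded[stats::complete.cases(coded[score_factor_names()]), ]
    totals <- total_score(scored, reference_score_table())
    keep <- totals >= 32 & totals <= 52
    rep_ <- category_report(totals[keep], scored$time[keep],
                            scored$event[keep], category_scheme("category4"))
    all(diff(rep_$five_year_rate) > 0)       # worst bin first, best last
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
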