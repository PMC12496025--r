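test_that("the DID pipeline recovers zero on a symmetric placebo cohort", {
  rows <- main_rows(placebo_cohort(seed = 31))
  fit <- run_average_did(rows)
  att <- dplyr::filter(tidy(fit), term == "att")
  expect_lt(abs(att$estimate), 3 * att$std.error)
  per <- run_period_did(rows)
  for (tm in per$effect_terms) {
    z <- dplyr::filter(tidy(per), term == tm)
    expect_lt(abs(z$estimate), 4 * z$std.error)
  }
})

test_that("saturated specification equals the raw difference-in-differences", {
  # two hospitals (one per country), single pre/post split, no covariates
  set.seed(41)
  n <- 400
  d <- tibble::tibble(
    country = rep(c("England", "Wales"), each = n / 2),
    hospital = rep(c("E1", "W1"), each = n / 2),
    post = rep(rep(0:1, each = n / 4), 2),
    y = rbinom(n, 1, 0.3 + 0.3 * (rep(c(1, 0), each = n / 2) *
                                    rep(rep(0:1, each = n / 4), 2)))
  )
  d$att <- as.integer(d$country == "England") * d$post
  fit <- fit_fe_lpm(d, y ~ att + post, fe = "hospital")
  m <- tapply(d$y, list(d$country, d$post), mean)
  raw <- (m["England", "1"] - m["England", "0"]) -
    (m["Wales", "1"] - m["Wales", "0"])
  expect_equal(coef(fit)[["att"]], raw, tolerance = 1e-10)
})

test_that("an injected treatment effect is recovered within its confidence interval", {
  delta <- 0.30
  cfg <- cohort_config(hospitals = list(England = c(25, 25), Wales = c(8, 8)),
                       patients_per_year = c(England = 1800, Wales = 500),
                       criterion_rho = 0.3, effect = list(bundle = delta),
                       seed = 77)
  rows <- main_rows(generate_cohort(flat_calibration(0.6, 0.3),
                                    patient_mix(), cfg))
  td <- tidy(run_average_did(rows), conf.int = TRUE) |>
    dplyr::filter(term == "att")
  expect_gt(delta, td$conf.low)
  expect_lt(delta, td$conf.high)
})

test_that("the average effect lies between the period-specific effects", {
  cfg <- small_config(seed = 55)
  rows <- main_rows(generate_cohort(config = cfg))
  avg <- coef(run_average_did(rows))[["att"]]
  per <- coef(run_period_did(rows))[c("att_P1", "att_P2", "att_P3")]
  expect_gt(avg, min(per) - 1e-8)
  expect_lt(avg, max(per) + 1e-8)
})

test_that("pre-trend interactions are saturated quarter-level contrasts", {
  # one hospital per country: quarter-by-country cells are saturated
  cfg <- cohort_config(hospitals = list(England = c(1, 1), Wales = c(1, 1)),
                       patients_per_year = c(England = 1500, Wales = 1500),
                       years = 2008:2009, criterion_rho = 0.2, seed = 13)
  rows <- build_outcomes(generate_cohort(flat_calibration(0.7, 0.2),
                                         patient_mix(), cfg))
  pt <- suppressWarnings(run_pretrend_test(rows, covariates = "none"))
  m <- tapply(rows$bundle_met, list(rows$england, rows$quarter), mean)
  for (k in 2:8) {
    did_k <- (m["1", as.character(k)] - m["1", "1"]) -
      (m["0", as.character(k)] - m["0", "1"])
    expect_equal(coef(pt$fit)[[paste0("tau", k)]], did_k, tolerance = 1e-10)
  }
})

test_that("pre-trend test is sized under the null and powered against drift", {
  rows <- main_rows(placebo_cohort(seed = 19))
  pt <- run_pretrend_test(rows)
  taus <- dplyr::filter(tidy(pt$fit), grepl("^tau", term))
  expect_true(all(abs(taus$estimate) < 4 * taus$std.error))
  expect_true(all(c("statistic", "p.value") %in% names(pt$joint)))
  expect_equal(pt$joint$df, 7)
  expect_equal(pt$joint_no_anticipation$df, 6)

  # England-only improvement in the second pre-year: taus rise, joint rejects
  cal_drift <- flat_calibration(0.6, 0.2)
  bump <- cal_drift$country == "England" & cal_drift$fy == 2009 &
    cal_drift$criterion != "bundle"
  cal_drift$prob[bump] <- 0.72
  b09 <- cal_drift$country == "England" & cal_drift$fy == 2009 &
    cal_drift$criterion == "bundle"
  cal_drift$prob[b09] <- joint_achievement_prob(rep(0.72, 7), 0.2)
  cfg <- small_config(seed = 23, criterion_rho = 0.2, years = 2008:2009)
  rows_d <- build_outcomes(generate_cohort(cal_drift, patient_mix(), cfg))
  pt_d <- run_pretrend_test(rows_d, covariates = "none")
  expect_lt(pt_d$joint$p.value, 0.01)
  taus_d <- dplyr::filter(tidy(pt_d$fit), grepl("^tau", term))
  expect_gt(mean(taus_d$estimate[4:7]), mean(taus_d$estimate[1:3]))

  expect_error(run_pretrend_test(rows[rows$quarter %in% c(1:6, NA), ]),
               "8 pre-policy quarters")
})

test_that("criterion-level loop returns the full effects table", {
  rows <- main_rows(placebo_cohort(seed = 91))
  tab <- run_criterion_effects(rows)
  expect_setequal(unique(tab$outcome), c(bpt_criteria(), "criteria_count"))
  expect_setequal(unique(tab$effect), c("average", "P1", "P2", "P3"))
  expect_equal(nrow(tab), 9 * 4)
  # placebo: criterion effects centred on zero
  avg <- tab[tab$effect == "average" & tab$outcome != "criteria_count", ]
  expect_true(all(abs(avg$estimate) < 4 * avg$std.error))
})

test_that("sensitivity variants behave as designed", {
  coh <- apply_missingness(generate_cohort(config = small_config(seed = 47)),
                           c(England = 0.15, Wales = 0.15))
  rows <- build_outcomes(coh)
  tab <- run_robustness_suite(rows)
  expect_setequal(unique(tab$variant),
                  c("main", "balanced_panel", "limited_casemix",
                    "seven_criteria", "no_anticipation"))
  avg <- function(v) tab$estimate[tab$variant == v & tab$effect == "average"]
  # no anticipation effect was generated: estimate moves little
  expect_lt(abs(avg("no_anticipation") - avg("main")), 0.05)
  # limited case-mix keeps every row
  expect_gt(tab$nobs[tab$variant == "limited_casemix"][1],
            tab$nobs[tab$variant == "main"][1])
})

test_that("dropping a binding eighth criterion shifts the effect upward", {
  # England achieves BPT4 rarely post-2012, so the 8-criterion bundle binds
  cal <- flat_calibration(0.9, 0.2)
  sel <- cal$country == "England" & cal$fy >= 2012
  cal$prob[sel & cal$criterion == "BPT4"] <- 0.3
  for (y in 2012:2014) {
    i <- cal$country == "England" & cal$fy == y & cal$criterion == "bundle"
    p <- cal$prob[cal$country == "England" & cal$fy == y &
                    cal$criterion %in% bpt_criteria()]
    cal$prob[i] <- joint_achievement_prob(p, 0.2)
  }
  cfg <- small_config(seed = 61, criterion_rho = 0.2)
  rows <- build_outcomes(apply_missingness(
    generate_cohort(cal, patient_mix(), cfg), c(England = 0.1, Wales = 0.1)))
  main <- filter_sample(rows, "main")
  seven <- filter_sample(rows, "seven_criteria")
  att_main <- coef(run_average_did(main))[["att"]]
  att_seven <- coef(run_average_did(seven))[["att"]]
  expect_gt(att_seven, att_main)
})
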