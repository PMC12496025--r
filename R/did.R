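# Reference categories used throughout the regression tables: age 60-64,
# female, admitted from hospital, ASA 1, full mobility, extracapsular,
# financial year 2008/09, April.
prepare_design <- function(rows) {
  rows |>
    dplyr::mutate(
      fy_f = factor(.data$fy),
      month_f = factor(.data$month, levels = c(4:12, 1:3)),
      age_band = factor(.data$age_band,
                        levels = c("60-64", "65-69", "70-74", "75-79",
                                   "80-84", "85-89", "90+")),
      sex = factor(.data$sex, levels = c("female", "male")),
      admission_source = factor(.data$admission_source,
                                levels = c("hospital", "care_home",
                                           "residential_home", "other")),
      asa = factor(.data$asa, levels = 1:5),
      mobility = factor(.data$mobility,
                        levels = c("full", "outdoor", "indoor", "none")),
      fracture_type = factor(.data$fracture_type,
                             levels = c("extracapsular", "intracapsular"))
    )
}

covariate_terms <- function(covariates = c("full", "limited", "none")) {
  switch(match.arg(covariates),
    full = c("age_band", "sex", "admission_source", "asa", "mobility",
             "fracture_type"),
    limited = c("age_band", "sex", "fracture_type"),
    none = character(0))
}

did_formula <- function(outcome, treat_terms, covariates,
                        time = c("fy_f", "month_f")) {
  rhs <- c(treat_terms, time, covariate_terms(covariates))
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")),
                    env = baseenv())
}

#' Average policy effect (difference-in-differences)
#'
#' Fits the base policy-evaluation model: a linear probability model of the
#' outcome on the England-times-post interaction, financial-year and
#' calendar-month dummies and the case-mix covariates, with hospital fixed
#' effects absorbed and hospital-clustered standard errors.  The country and
#' post main effects are intentionally omitted: the country level is absorbed
#' by the hospital effects and the post level by the year dummies, so only
#' the interaction — the average treatment effect on the treated — is
#' identified.
#'
#' @param rows Analysis rows from [build_outcomes()], already filtered to the
#'   estimation sample (e.g. via [filter_sample()]); must span both countries
#'   and both policy periods.
#' @param outcome Outcome column name (default the bundle indicator).
#' @param covariates `"full"`, `"limited"` (age, sex, fracture type) or
#'   `"none"`.
#' @return A `cb_fit`; the interaction coefficient is named `att`.
#' @export
run_average_did <- function(rows, outcome = "bundle_met", covariates = "full") {
  if (length(unique(rows$country)) < 2 || length(unique(rows$post)) < 2) {
    abort("rows must include both countries and both pre- and post-policy periods")
  }
  d <- prepare_design(rows)
  d$att <- d$england * d$post
  fit <- fit_fe_lpm(d, did_formula(outcome, "att", covariates))
  fit$effect_terms <- "att"
  fit
}

#' Period-specific policy effects
#'
#' As [run_average_did()], but with separate interactions for the three
#' post-policy bonus periods: April 2010--March 2011 (bonus £445),
#' April 2011--March 2012 (£890) and April 2012--March 2015 (£1335).
#'
#' @inheritParams run_average_did
#' @return A `cb_fit` with effect coefficients `att_P1`, `att_P2`, `att_P3`.
#' @export
run_period_did <- function(rows, outcome = "bundle_met", covariates = "full") {
  if (length(unique(rows$country)) < 2 || length(unique(rows$post)) < 2) {
    abort("rows must include both countries and both pre- and post-policy periods")
  }
  d <- prepare_design(rows)
  for (p in c("P1", "P2", "P3")) {
    d[[paste0("att_", p)]] <- d$england * as.integer(d$period == p)
  }
  fit <- fit_fe_lpm(d, did_formula(outcome, c("att_P1", "att_P2", "att_P3"),
                                   covariates))
  fit$effect_terms <- c("att_P1", "att_P2", "att_P3")
  fit
}

#' Pre-policy parallel-trends (event-study) test
#'
#' Uses only pre-policy admissions (April 2008 -- March 2010), divided into
#' eight quarters, and estimates country-specific quarter deviations: quarter
#' dummies plus England-by-quarter interactions (`tau2` ... `tau8`, the first
#' quarter being the reference), case-mix covariates and hospital fixed
#' effects.  Under parallel trends all interactions are zero.  Quarter
#' dummies already absorb within-window seasonal-by-year variation, so no
#' separate calendar-month dummies enter (they would be exactly collinear
#' with the quarter dummies over a two-year window).
#'
#' Returns the fit plus two joint Wald tests — over all seven interactions,
#' and excluding the final pre-policy quarter (January--March 2010, the
#' potential anticipation period) — and the corresponding summed-deviation
#' linear combinations.
#'
#' @inheritParams run_average_did
#' @return A list of class `"cb_pretrend"`: `fit`, `joint`,
#'   `joint_no_anticipation`, `sum_tau`, `sum_tau_no_anticipation`.
#' @export
run_pretrend_test <- function(rows, outcome = "bundle_met", covariates = "full") {
  pre <- rows[rows$post == 0, ]
  if (length(stats::na.omit(unique(pre$quarter))) < 8) {
    abort("pre-trend test needs all 8 pre-policy quarters")
  }
  d <- prepare_design(pre)
  d$quarter_f <- factor(d$quarter, levels = 1:8)
  tau <- paste0("tau", 2:8)
  for (k in 2:8) {
    d[[paste0("tau", k)]] <- d$england * as.integer(d$quarter == k)
  }
  fit <- fit_fe_lpm(d, did_formula(outcome, c("quarter_f", tau), covariates,
                                   time = character(0)))
  fit$effect_terms <- tau
  joint_safe <- function(terms) {
    tryCatch(wald_joint(fit, terms), error = function(e) {
      warn(paste("joint test unavailable:", conditionMessage(e)))
      tibble::tibble(statistic = NA_real_, df = length(terms),
                     p.value = NA_real_, p.chisq = NA_real_)
    })
  }
  structure(list(
    fit = fit,
    joint = joint_safe(tau),
    joint_no_anticipation = joint_safe(paste0("tau", 2:7)),
    sum_tau = lin_comb(fit, tau),
    sum_tau_no_anticipation = lin_comb(fit, paste0("tau", 2:7))
  ), class = "cb_pretrend")
}

#' @export
print.cb_pretrend <- function(x, ...) {
  cat("Pre-policy parallel-trends test\n")
  print(dplyr::filter(x$fit$coefficients, grepl("^tau", .data$term)))
  cat(sprintf("Joint test (all quarters): chi2 = %.3f, p(F) = %.4f\n",
              x$joint$statistic, x$joint$p.value))
  cat(sprintf("Joint test minus anticipation quarter: chi2 = %.3f, p(F) = %.4f\n",
              x$joint_no_anticipation$statistic, x$joint_no_anticipation$p.value))
  invisible(x)
}

#' Policy effects for each care-process criterion and the criterion count
#'
#' Re-estimates the average and period-specific models with each of the
#' eight criterion indicators and the number-of-criteria-met count as the
#' outcome.
#'
#' @inheritParams run_average_did
#' @return A tibble with columns `outcome`, `effect` (`average`, `P1`, `P2`,
#'   `P3`), `estimate`, `std.error`, `p.value`, `nobs`, `n_clusters`.
#' @export
run_criterion_effects <- function(rows, covariates = "full") {
  outcomes <- c(bpt_criteria(), "criteria_count")
  purrr::map_dfr(outcomes, function(oc) {
    avg <- run_average_did(rows, oc, covariates)
    per <- run_period_did(rows, oc, covariates)
    dplyr::bind_rows(
      dplyr::filter(tidy(avg), .data$term == "att") |>
        dplyr::mutate(effect = "average"),
      dplyr::filter(tidy(per), .data$term %in% per$effect_terms) |>
        dplyr::mutate(effect = sub("att_", "", .data$term))
    ) |>
      dplyr::transmute(outcome = oc, effect = .data$effect,
                       estimate = .data$estimate, std.error = .data$std.error,
                       p.value = .data$p.value, nobs = avg$nobs,
                       n_clusters = avg$n_clusters)
  })
}

#' Sensitivity-analysis suite
#'
#' Runs the average and period-specific models under the sample variants of
#' [filter_sample()]: main sample, balanced hospital panel, limited case-mix
#' adjustment, the seven-criterion bundle definition, and exclusion of the
#' six-month anticipation window.
#'
#' @param rows Analysis rows from [build_outcomes()] *before* the main
#'   covariate filter (i.e. retaining rows with masked covariates), so each
#'   variant can apply its own filter.
#' @param outcome Outcome column name.
#' @return A tibble with columns `variant`, `effect`, `estimate`,
#'   `std.error`, `p.value`, `nobs`, `n_clusters`.
#' @export
run_robustness_suite <- function(rows, outcome = "bundle_met") {
  variants <- c("main", "balanced_panel", "limited_casemix", "seven_criteria",
                "no_anticipation")
  purrr::map_dfr(variants, function(v) {
    sub <- filter_sample(rows, v)
    if (nrow(sub) == 0) abort(paste("variant", v, "produced an empty sample"))
    cov <- if (v == "limited_casemix") "limited" else "full"
    avg <- run_average_did(sub, outcome, cov)
    per <- run_period_did(sub, outcome, cov)
    dplyr::bind_rows(
      dplyr::filter(tidy(avg), .data$term == "att") |>
        dplyr::mutate(effect = "average"),
      dplyr::filter(tidy(per), .data$term %in% per$effect_terms) |>
        dplyr::mutate(effect = sub("att_", "", .data$term))
    ) |>
      dplyr::transmute(variant = v, effect = .data$effect,
                       estimate = .data$estimate, std.error = .data$std.error,
                       p.value = .data$p.value, nobs = avg$nobs,
                       n_clusters = avg$n_clusters)
  })
}
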