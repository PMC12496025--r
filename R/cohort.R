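#' Configuration of the synthetic audit cohort
#'
#' Controls the structure of the generated patient-level records: the growing
#' hospital panel, cluster sizes, the latent correlation structure of the
#' care-process indicators, covariate missingness, and optional injected
#' treatment effects for parameter-recovery experiments.
#'
#' @param hospitals Named list of `c(start, end)` hospital counts per country;
#'   counts grow linearly (rounded) across financial years 2008--2014.
#' @param patients_per_year Optional named vector of total patients per
#'   country per financial year (patients are spread evenly across that
#'   year's hospitals).  When `NULL`, per-hospital-year counts are drawn from
#'   a negative binomial with mean `mean_patients` and dispersion `nb_size`
#'   (overdispersed cluster sizes).
#' @param mean_patients Named vector of mean patients per hospital-year.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param hospital_icc Share of latent-scale variance attributable to a
#'   persistent hospital intercept, inducing within-hospital clustering of
#'   achievement; in `[0, 1)`.
#' @param criterion_rho Either `NULL` (default: per country-year exchangeable
#'   correlation solved so the joint achievement of the era bundle set matches
#'   the calibration's `bundle` row, see
#'   [calibrate_bundle_correlation()]) or a scalar total latent correlation
#'   applied to every country-year.
#' @param missingness Named per-country probability that a patient's
#'   maskable covariates (admission source, ASA grade, mobility) are recorded
#'   as missing.  Age, sex and fracture type are always recorded, and
#'   care-process indicators are never masked (unachieved is coded 0).
#' @param asa_gradient Optional latent-scale shift per ASA grade away from
#'   grade 3, making achievement decline with operative risk (default 0
#'   keeps the calibration marginals exact).
#' @param effect Optional injected treatment effect for England in the
#'   post-policy period (financial years 2010+): a named list such as
#'   `list(bundle = 0.30)` (raises the bundle achievement probability by
#'   exactly 0.30 in every post year via a patient-level mixture that forces
#'   the full criterion set) and/or per-criterion entries such as
#'   `list(BPT1 = 0.10)`.
#' @param sequential_effect Optional probability drop injected into the
#'   chance that England post-policy patients who missed at least one
#'   pre-surgery criterion achieve all post-surgery criteria (used to
#'   validate the sequential decision-making estimator).
#' @param years Financial years to generate (subset of 2008:2014).
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   cohort exactly.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(hospitals = list(England = c(105, 165), Wales = c(5, 13)),
                          patients_per_year = NULL,
                          mean_patients = c(England = 320, Wales = 270),
                          nb_size = 8,
                          hospital_icc = 0.05,
                          criterion_rho = NULL,
                          missingness = c(England = 0.175, Wales = 0.188),
                          asa_gradient = 0,
                          effect = NULL,
                          sequential_effect = NULL,
                          years = 2008:2014,
                          seed = 1) {
  stopifnot(hospital_icc >= 0, hospital_icc < 1,
            all(missingness >= 0), all(missingness <= 1),
            all(years %in% 2008:2014))
  if (!is.null(criterion_rho)) stopifnot(criterion_rho >= 0, criterion_rho < 1)
  structure(list(hospitals = hospitals, patients_per_year = patients_per_year,
                 mean_patients = mean_patients, nb_size = nb_size,
                 hospital_icc = hospital_icc, criterion_rho = criterion_rho,
                 missingness = missingness, asa_gradient = asa_gradient,
                 effect = effect, sequential_effect = sequential_effect,
                 years = sort(years), seed = seed),
            class = "cohort_config")
}

# Hospital roster: linear growth in counts across the 7 study years; hospital
# i is present from the first year in which the count reaches i.
hospital_roster <- function(hospitals) {
  purrr::imap_dfr(hospitals, function(range, country) {
    counts <- round(seq(range[1], range[2], length.out = 7))
    join <- vapply(seq_len(range[2]),
                   function(i) (2008:2014)[which(counts >= i)[1]], integer(1))
    tibble::tibble(
      hospital = sprintf("%s%03d", substr(country, 1, 1), seq_len(range[2])),
      country = country, join_year = join
    )
  })
}

# Correlation of the criterion-specific latent shocks, net of the hospital
# intercept: total = icc + (1 - icc) * r.
shock_correlation <- function(rho_total, icc, k) {
  r <- (rho_total - icc) / (1 - icc)
  if (r < -1 / (k - 1) + 1e-9) {
    abort(sprintf(paste0("infeasible criterion correlation: total %.3f with ",
                         "hospital ICC %.3f requires shock correlation %.3f < -1/(k-1)"),
                  rho_total, icc, r))
  }
  R <- matrix(r, k, k); diag(R) <- 1
  R
}

sample_categorical <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic hip-fracture audit cohort
#'
#' Simulates patient-level records with the structure of a national clinical
#' audit: hospital membership in a growing England/Wales panel, monthly
#' admission dates April 2008--March 2015, categorical case-mix covariates
#' drawn from [patient_mix()], and eight binary care-process indicators
#' (BPT1--BPT4, BPT6--BPT9) whose per country-year marginals match the
#' calibration table and whose within-patient dependence follows a latent
#' Gaussian threshold model with a persistent hospital intercept.
#'
#' @param calibration Calibration tibble ([bpt_calibration()] layout).
#' @param mix Covariate marginals ([patient_mix()] layout).
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `patient_id`, `hospital`,
#'   `country`, `admission_date` (first of month), covariates (`age_band`,
#'   `sex`, `admission_source`, `asa`, `mobility`, `fracture_type`) and the
#'   eight criterion indicator columns (0/1).  Covariates are complete;
#'   apply [apply_missingness()] to emulate audit missingness.
#' @examples
#' cfg <- cohort_config(patients_per_year = c(England = 400, Wales = 100),
#'                      years = 2009:2010, seed = 42)
#' cohort <- generate_cohort(config = cfg)
#' @export
generate_cohort <- function(calibration = bpt_calibration(),
                            mix = patient_mix(),
                            config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  crit <- bpt_criteria()
  k <- length(crit)
  icc <- config$hospital_icc

  rho_tab <- if (is.null(config$criterion_rho)) {
    calibrate_bundle_correlation(calibration)
  } else {
    dplyr::distinct(calibration, .data$country, .data$fy) |>
      dplyr::mutate(rho = config$criterion_rho)
  }

  roster <- hospital_roster(config$hospitals)
  u_h <- setNames(rnorm(nrow(roster)), roster$hospital)

  out <- list()
  for (country in names(config$hospitals)) {
    mix_c <- mix[mix$country == country, ]
    for (fy in config$years) {
      hosp <- roster$hospital[roster$country == country & roster$join_year <= fy]
      n_h <- length(hosp)
      if (is.null(config$patients_per_year)) {
        sizes <- rnbinom(n_h, size = config$nb_size,
                         mu = config$mean_patients[[country]])
      } else {
        total <- config$patients_per_year[[country]]
        sizes <- tabulate(sample.int(n_h, total, replace = TRUE), nbins = n_h)
      }
      n <- sum(sizes)
      if (n == 0) next
      hospital <- rep(hosp, sizes)

      p <- calibration$prob[calibration$country == country &
                              calibration$fy == fy][
        match(crit, calibration$criterion[calibration$country == country &
                                            calibration$fy == fy])]
      rho <- rho_tab$rho[rho_tab$country == country & rho_tab$fy == fy]
      R <- shock_correlation(rho, icc, k)
      eps <- matrix(rnorm(n * k), n, k) %*% chol(R)
      z <- sqrt(icc) * u_h[hospital] + sqrt(1 - icc) * eps

      rec <- tibble::tibble(hospital = hospital, country = country)
      for (v in unique(mix_c$variable)) {
        sub <- mix_c[mix_c$variable == v, ]
        rec[[v]] <- sample_categorical(n, sub$level, sub$prob)
      }
      if (config$asa_gradient != 0) {
        z <- z + config$asa_gradient * (as.numeric(rec$asa) - 3)
      }
      ach <- sweep(z, 2, qnorm(p), "<") * 1L
      colnames(ach) <- crit

      # injected effects (England, post-policy years only)
      if (country == "England" && fy >= 2010) {
        era_set <- if (fy >= 2012) bundle_set_late() else bundle_set_early()
        if (!is.null(config$effect)) {
          for (nm in names(config$effect)) {
            delta <- config$effect[[nm]]
            if (nm == "bundle") {
              p0 <- joint_achievement_prob(p[match(era_set, crit)], rho)
              kappa <- delta / (1 - p0)
              force <- runif(n) < kappa
              ach[force, ] <- 1L
            } else {
              pc <- p[match(nm, crit)]
              kappa <- delta / (1 - pc)
              force <- runif(n) < kappa
              ach[force, nm] <- 1L
            }
          }
        }
        if (!is.null(config$sequential_effect)) {
          idx_pre <- match(pre_surgery_set(), crit)
          idx_post <- match(post_surgery_set(), crit)
          p_post <- joint_achievement_prob(p[idx_post], rho)
          p_all <- joint_achievement_prob(p[union(idx_pre, idx_post)], rho)
          p_pre <- joint_achievement_prob(p[idx_pre], rho)
          p_cond <- (p_post - p_all) / (1 - p_pre)
          kappa <- min(config$sequential_effect / p_cond, 1)
          pre_missed <- rowSums(ach[, idx_pre, drop = FALSE]) < length(idx_pre)
          force <- pre_missed & runif(n) < kappa
          ach[force, idx_post] <- 0L
        }
      }

      month <- sample.int(12, n, replace = TRUE)       # 1 = April ... 12 = March
      cal_month <- (month + 2) %% 12 + 1
      cal_year <- fy + (cal_month < 4)
      rec$admission_date <- as.Date(sprintf("%d-%02d-01", cal_year, cal_month))
      out[[length(out) + 1]] <- dplyr::bind_cols(rec, tibble::as_tibble(ach))
    }
  }
  cohort <- dplyr::bind_rows(out)
  cohort |>
    dplyr::mutate(patient_id = sprintf("P%07d", dplyr::row_number()),
                  asa = as.integer(.data$asa)) |>
    dplyr::select("patient_id", "hospital", "country", "admission_date",
                  "age_band", "sex", "admission_source", "asa", "mobility",
                  "fracture_type", dplyr::all_of(crit))
}

#' Configuration for the calibrated reproduction of the published effects
#'
#' The canonical design for reproducing the published policy effects from the
#' packaged calibration table: a constant full-size hospital panel (165
#' England, 13 Wales in every year) with equal patients per financial year
#' (3600 England, 700 Wales; about 30,000 patients over 2008/09--2014/15) and
#' default clustering and missingness.  The panel is held constant because
#' pairing panel growth with fixed yearly patient totals would shrink
#' incumbent hospitals' post-period weight and attenuate the two-way
#' fixed-effects average of time-varying effects — an artifact of fixing the
#' totals, not a feature of the audit, whose volume grew with participation.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
reproduction_config <- function(seed = 1) {
  cohort_config(hospitals = list(England = c(165, 165), Wales = c(13, 13)),
                patients_per_year = c(England = 3600, Wales = 700),
                seed = seed)
}

#' Mask covariates to emulate audit missingness
#'
#' With country-specific probability, a patient's maskable covariates
#' (admission source, ASA grade, pre-fracture mobility) are set to `NA`,
#' completely at random.  Age, sex and fracture type are recorded for every
#' patient, and care-process indicators are never masked: an unachieved or
#' unrecorded criterion is coded 0 upstream.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param rates Named per-country masking probability.
#' @param seed Optional seed for the masking draw.
#' @return The cohort with `NA`s in the maskable covariate columns.
#' @export
apply_missingness <- function(cohort,
                              rates = c(England = 0.175, Wales = 0.188),
                              seed = NULL) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  rate <- unname(rates[cohort$country])
  masked <- runif(nrow(cohort)) < rate
  for (v in c("admission_source", "asa", "mobility")) {
    cohort[[v]][masked] <- NA
  }
  cohort
}
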