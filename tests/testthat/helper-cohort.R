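# Shared fixtures, built in code at test time.

# Small proportionate panel: big enough for the balanced-panel variant
# (>= 30 patients per hospital-year) yet quick to generate and fit.
small_config <- function(seed = 1, ...) {
  cohort_config(hospitals = list(England = c(20, 30), Wales = c(5, 8)),
                patients_per_year = c(England = 2500, Wales = 600),
                seed = seed, ...)
}

# Symmetric no-effect design: identical calibration in both countries, so
# every DID estimand is exactly zero.
placebo_cohort <- function(seed = 1, p = 0.7, rho = 0.3, ...) {
  cfg <- small_config(seed = seed, criterion_rho = rho, ...)
  generate_cohort(flat_calibration(p, rho), patient_mix(), cfg)
}

# Analysis rows for a calibrated cohort, main estimation sample.
main_rows <- function(cohort, rates = c(England = 0.175, Wales = 0.188)) {
  filter_sample(build_outcomes(apply_missingness(cohort, rates)), "main")
}

# Hand-rolled 2x2 design with exact cell means: n per cell, mean achieved by
# placing round(n * m) successes.
saturated_2x2 <- function(n = 40, m_e_pre = 0.1, m_e_post = 0.6,
                          m_w_pre = 0.1, m_w_post = 0.2) {
  cell <- function(country, post, m) {
    tibble::tibble(country = country, post = post,
                   y = rep(c(1, 0), c(round(n * m), n - round(n * m))))
  }
  dplyr::bind_rows(cell("England", 0, m_e_pre), cell("England", 1, m_e_post),
                   cell("Wales", 0, m_w_pre), cell("Wales", 1, m_w_post)) |>
    dplyr::mutate(att = as.integer(country == "England") * post)
}
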