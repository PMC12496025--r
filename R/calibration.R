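#' Packaged care-process achievement calibration table
#'
#' Loads the per-country, per-financial-year proportion of hip-fracture
#' patients achieving each Best Practice Tariff criterion (BPT1--BPT4,
#' BPT6--BPT9) and the full care bundle, for England and Wales over financial
#' years 2008/09--2014/15.  These proportions are the calibration targets of
#' the synthetic cohort generator.  Financial years run from 1 April to 31
#' March and are labelled by their starting calendar year.
#'
#' @param path Optional path to a CSV with the same layout (columns `country`,
#'   `criterion`, `fy2008` ... `fy2014`); defaults to the packaged table.
#' @return A tibble with columns `country`, `criterion` (`"bundle"` or a BPT
#'   label), `fy` (integer 2008--2014) and `prob`.
#' @examples
#' cal <- bpt_calibration()
#' dplyr::filter(cal, country == "England", fy == 2010)
#' @export
bpt_calibration <- function(path = system.file("extdata", "bpt_achievement.csv",
                                               package = "carebundles")) {
  raw <- read.csv(path, check.names = FALSE)
  cal <- raw |>
    tidyr::pivot_longer(dplyr::starts_with("fy"), names_to = "fy",
                        names_prefix = "fy", values_to = "prob") |>
    dplyr::mutate(fy = as.integer(.data$fy)) |>
    dplyr::arrange(.data$country, .data$criterion, .data$fy) |>
    dplyr::as_tibble()
  expected <- nrow(tidyr::expand_grid(country = c("England", "Wales"),
                                      criterion = c("bundle", bpt_criteria()),
                                      fy = 2008:2014))
  if (nrow(dplyr::distinct(cal, .data$country, .data$criterion, .data$fy)) != expected ||
      nrow(cal) != expected) {
    abort("calibration grid is incomplete: need 2 countries x 9 rows x 7 financial years")
  }
  if (any(cal$prob < 0 | cal$prob > 1)) abort("calibration probabilities must lie in [0, 1]")
  cal
}

#' Packaged patient-mix marginals
#'
#' Categorical covariate distributions per country: sex, admission source,
#' ASA grade, pre-fracture mobility and fracture type come from the published
#' descriptive statistics; age-band probabilities are a synthetic
#' construction (file `age_bands_synthetic.csv`) chosen to match the
#' published mean age of about 82.5 years, as band-level frequencies are not
#' published.  Each distribution is renormalised to sum to exactly 1.
#'
#' @return A tibble with columns `country`, `variable`, `level`, `prob`.
#' @export
patient_mix <- function() {
  mix <- dplyr::bind_rows(
    read.csv(system.file("extdata", "patient_mix.csv", package = "carebundles")),
    read.csv(system.file("extdata", "age_bands_synthetic.csv", package = "carebundles"))
  ) |>
    dplyr::group_by(.data$country, .data$variable) |>
    dplyr::mutate(prob = .data$prob / sum(.data$prob)) |>
    dplyr::ungroup() |>
    dplyr::as_tibble()
  mix
}

#' Joint probability that all criteria are achieved under an exchangeable
#' Gaussian copula
#'
#' Criterion indicators are modelled as thresholded latent Gaussians with
#' common pairwise correlation `rho`: indicator `j` is achieved iff
#' `z_j < qnorm(p_j)` where `z` is standard multivariate normal with
#' equicorrelation `rho`.  For `rho >= 0` the single-factor representation
#' `z_j = sqrt(rho) u + sqrt(1 - rho) e_j` reduces the joint probability to a
#' one-dimensional integral, evaluated by adaptive quadrature.
#'
#' @param p Vector of marginal achievement probabilities.
#' @param rho Common latent correlation in `[0, 1)`.
#' @return The probability that all indicators equal 1.
#' @examples
#' joint_achievement_prob(c(0.9, 0.8, 0.7), 0.3)
#' @export
joint_achievement_prob <- function(p, rho) {
  stopifnot(rho >= 0, rho < 1, all(p >= 0), all(p <= 1))
  if (any(p == 0)) return(0)
  p <- p[p < 1]                       # criteria with p = 1 are always met
  if (length(p) == 0) return(1)
  if (rho < 1e-12) return(prod(p))
  t <- qnorm(p)
  f <- function(u) {
    dnorm(u) * vapply(u, function(ui)
      prod(pnorm((t - sqrt(rho) * ui) / sqrt(1 - rho))), numeric(1))
  }
  integrate(f, -8.5, 8.5, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Memoised per-cell solver: find the exchangeable latent correlation that
# makes the joint probability over the era criterion set match the bundle
# target.  Targets outside the attainable range [prod(p), min(p)) clamp to
# the nearest endpoint of the search interval [0, 0.995].
cal_memo <- new.env(parent = emptyenv())

solve_bundle_rho <- function(p, target, lo = 0, hi = 0.995) {
  key <- paste(signif(c(p, target), 8), collapse = "|")
  hit <- cal_memo[[key]]
  if (!is.null(hit)) return(hit)
  pl <- joint_achievement_prob(p, lo)
  ph <- joint_achievement_prob(p, hi)
  rho <- if (target <= pl) lo else if (target >= ph) hi else
    uniroot(function(r) joint_achievement_prob(p, r) - target,
            c(lo, hi), tol = 1e-9)$root
  cal_memo[[key]] <- rho
  rho
}

#' Calibrate the latent criterion correlation to the bundle achievement row
#'
#' For each country and financial year, solves for the exchangeable latent
#' correlation under which the joint probability of achieving every criterion
#' in that year's bundle set (seven criteria before April 2012, eight
#' including BPT4 thereafter) equals the calibrated bundle proportion.
#'
#' @param calibration A calibration table as returned by [bpt_calibration()].
#' @return A tibble with one row per `country` x `fy`: the solved `rho`, the
#'   bundle `target` and the `achieved` joint probability (equal to the
#'   target except where the target lies outside the attainable range and the
#'   correlation clamps at an endpoint).
#' @export
calibrate_bundle_correlation <- function(calibration) {
  cells <- dplyr::distinct(calibration, .data$country, .data$fy)
  purrr::pmap_dfr(cells, function(country, fy) {
    set <- if (fy >= 2012) bundle_set_late() else bundle_set_early()
    sub <- calibration[calibration$country == country & calibration$fy == fy, ]
    p <- sub$prob[match(set, sub$criterion)]
    target <- sub$prob[sub$criterion == "bundle"]
    rho <- solve_bundle_rho(p, target)
    tibble::tibble(country = country, fy = fy, rho = rho, target = target,
                   achieved = joint_achievement_prob(p, rho))
  })
}

#' Flat synthetic calibration for placebo and recovery experiments
#'
#' Builds a calibration table with the same achievement probability `p` for
#' every criterion in both countries and all years, and a bundle row equal to
#' the joint probability implied by an exchangeable latent correlation `rho`.
#' Because the two countries are exchangeable by construction, any downstream
#' difference-in-differences estimand is exactly zero, which makes this the
#' canonical input for size, placebo and parameter-recovery simulations.
#'
#' @param p Common marginal achievement probability.
#' @param rho Common latent correlation.
#' @return A calibration tibble in the [bpt_calibration()] layout.
#' @examples
#' flat_calibration(p = 0.7, rho = 0.3)
#' @export
flat_calibration <- function(p = 0.7, rho = 0.3) {
  grid <- tidyr::expand_grid(country = c("England", "Wales"), fy = 2008:2014)
  crit <- tidyr::expand_grid(grid, criterion = bpt_criteria()) |>
    dplyr::mutate(prob = p)
  bundle <- grid |>
    dplyr::mutate(
      criterion = "bundle",
      prob = ifelse(.data$fy >= 2012,
                    joint_achievement_prob(rep(p, 8), rho),
                    joint_achievement_prob(rep(p, 7), rho))
    )
  dplyr::bind_rows(crit, bundle) |>
    dplyr::select("country", "criterion", "fy", "prob") |>
    dplyr::arrange(.data$country, .data$criterion, .data$fy)
}
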