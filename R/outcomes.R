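#' Financial year of an admission date
#'
#' UK NHS financial years run from 1 April to 31 March and are labelled by
#' the starting calendar year: April--December map to that year's financial
#' year, January--March to the previous one.
#'
#' @param date A `Date` vector.
#' @return Integer financial year.
#' @examples
#' financial_year(as.Date(c("2010-03-15", "2010-04-01")))  # 2009, 2010
#' @export
financial_year <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - (m < 4L)
}

#' Build analysis variables from a patient cohort
#'
#' Appends the outcome and design variables used by the estimation pipeline:
#' the financial year, calendar month, post-policy indicator (admissions from
#' April 2010), bonus-period index (P1: 2010/11, P2: 2011/12, P3:
#' 2012/13--2014/15), pre-policy quarter index (1--8 over April 2008--March
#' 2010), the all-or-nothing bundle indicator and the count of criteria met.
#'
#' The bundle requires all seven initial criteria (BPT1--BPT3, BPT6--BPT9)
#' before April 2012 and additionally BPT4 from April 2012, when it entered
#' the payment rule.  The count outcome uses the same era-specific criterion
#' set by default; set `count_all_criteria = TRUE` to always count all eight.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (criterion columns
#'   must be complete; unachieved is coded 0).
#' @param count_all_criteria Count all eight criteria in every era?
#' @return The cohort with columns `fy`, `month`, `post`, `period`,
#'   `quarter`, `bundle_met`, `criteria_count`, and `england`.
#' @export
build_outcomes <- function(cohort, count_all_criteria = FALSE) {
  stopifnot(all(bpt_criteria() %in% names(cohort)))
  date <- as.Date(cohort$admission_date)
  fy <- financial_year(date)
  if (any(fy < 2008 | fy > 2014)) abort("admission dates outside the study window April 2008 - March 2015")
  month <- as.integer(format(date, "%m"))
  late_era <- fy >= 2012

  early <- bundle_set_early()
  met_early <- rowSums(as.matrix(cohort[early])) == length(early)
  met_late <- met_early & cohort$BPT4 == 1
  count_early <- rowSums(as.matrix(cohort[early]))
  count_late <- count_early + cohort$BPT4

  q <- (fy - 2008) * 4 + (match(month, c(4:12, 1:3)) - 1) %/% 3 + 1

  cohort |>
    dplyr::mutate(
      fy = fy,
      month = month,
      post = as.integer(fy >= 2010),
      period = dplyr::case_when(fy < 2010 ~ "pre", fy == 2010 ~ "P1",
                                fy == 2011 ~ "P2", .default = "P3"),
      quarter = ifelse(fy < 2010, q, NA_integer_),
      bundle_met = as.integer(ifelse(late_era, met_late, met_early)),
      criteria_count = if (count_all_criteria) count_early + cohort$BPT4
                       else ifelse(late_era, count_late, count_early),
      england = as.integer(.data$country == "England")
    )
}

#' Apply a sample filter variant
#'
#' Reproduces the estimation-sample definitions used by the main and
#' sensitivity analyses:
#' * `main`: drop patients with any missing covariate.
#' * `balanced_panel`: keep hospitals present in every financial year of the
#'   data with at least 30 patients in each year (then apply the `main`
#'   covariate filter).
#' * `limited_casemix`: keep all patients; downstream fits adjust only for
#'   age, sex and fracture type (which are never missing).
#' * `seven_criteria`: redefine `bundle_met` using the seven initial criteria
#'   (excluding BPT4) in all years; `main` covariate filter applies.
#' * `no_anticipation`: `main` filter plus exclusion of admissions in the six
#'   months before the policy start (October 2009 -- March 2010).
#'
#' @param rows Output of [build_outcomes()] (possibly after
#'   [apply_missingness()]).
#' @param variant One of the five variant names.
#' @return The filtered (and for `seven_criteria`, re-derived) tibble, with
#'   an attribute `variant`.
#' @export
filter_sample <- function(rows, variant = c("main", "balanced_panel",
                                            "limited_casemix", "seven_criteria",
                                            "no_anticipation")) {
  variant <- match.arg(variant)
  covars <- c("age_band", "sex", "admission_source", "asa", "mobility",
              "fracture_type")
  complete <- !Reduce(`|`, lapply(rows[covars], is.na))
  out <- switch(variant,
    main = rows[complete, ],
    balanced_panel = {
      years <- sort(unique(rows$fy))
      keep <- rows |>
        dplyr::count(.data$hospital, .data$fy) |>
        dplyr::group_by(.data$hospital) |>
        dplyr::summarise(ok = dplyr::n() == length(years) & all(.data$n >= 30)) |>
        dplyr::filter(.data$ok) |>
        dplyr::pull(.data$hospital)
      rows[complete & rows$hospital %in% keep, ]
    },
    limited_casemix = rows,
    seven_criteria = {
      early <- bundle_set_early()
      r <- rows[complete, ]
      r$bundle_met <- as.integer(rowSums(as.matrix(r[early])) == length(early))
      r
    },
    no_anticipation = {
      antic <- (rows$fy == 2009 & rows$month %in% c(10:12, 1:3))
      rows[complete & !antic, ]
    }
  )
  attr(out, "variant") <- variant
  out
}
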