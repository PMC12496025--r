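#' Build rows for the sequential decision-making analysis
#'
#' Under an all-or-nothing bundle, the financial incentive to deliver the
#' remaining care processes disappears as soon as one process has been
#' missed.  This analysis contrasts achievement of the post-surgery criteria
#' (BPT7 rehabilitation, BPT8 falls prevention, BPT9 bone health) between
#' patients who did and did not miss at least one pre/mid-surgery criterion
#' (BPT1 timely surgery, BPT3 care protocol, BPT4 cognitive assessment, BPT6
#' perioperative geriatric assessment).  BPT2 is excluded because its
#' control-country achievement is consistently low; only post-policy
#' admissions (April 2010 onward) enter.
#'
#' @param rows Analysis rows from [build_outcomes()].
#' @param include_bpt4_pre2012 Include BPT4 in the pre-surgery set for
#'   2010--2011 admissions, when it was recorded but not yet incentivized?
#'   Default `TRUE` (the set is defined clinically, not by payment era);
#'   `FALSE` restricts BPT4 to April 2012 onward.
#' @return The post-policy rows with `pre_missed` (1 if any pre-surgery
#'   criterion missed) and `post_all` (1 if every post-surgery criterion
#'   met).
#' @export
build_sequential_rows <- function(rows, include_bpt4_pre2012 = TRUE) {
  post <- rows[rows$post == 1, ]
  pre_set <- pre_surgery_set()
  pre_mat <- as.matrix(post[pre_set])
  if (!include_bpt4_pre2012) {
    # treat BPT4 as met (i.e. not countable as a miss) before April 2012
    pre_mat[post$fy < 2012, "BPT4"] <- 1L
  }
  post$pre_missed <- as.integer(rowSums(pre_mat) < ncol(pre_mat))
  post$post_all <- as.integer(rowSums(as.matrix(post[post_surgery_set()])) ==
                                length(post_surgery_set()))
  post
}

#' Effect of failing a pre-surgery criterion on post-surgery achievement
#'
#' Linear model of the all-post-surgery-criteria indicator on the
#' pre-surgery-miss indicator, a country main effect, and their interaction,
#' with hospital-clustered standard errors.  Three variants mirror
#' increasingly adjusted columns: `"observed"` (raw contrasts, no controls),
#' `"adjusted"` (plus time dummies and case-mix covariates), and `"fe"`
#' (additionally absorbing hospital fixed effects; the country main effect is
#' then unidentified and omitted).
#'
#' The interaction captures whether treated-country providers relax effort on
#' later processes once the bonus is no longer attainable for a patient; the
#' `pre_missed` main effect captures the common within-patient shortfall.
#'
#' @param rows Output of [build_sequential_rows()].
#' @param variant `"observed"`, `"adjusted"` or `"fe"`.
#' @param covariates Covariate set for the adjusted variants.
#' @return A `cb_fit` with effect coefficients `pre_missed`, `england` (except
#'   under `"fe"`) and `pre_x_england`.
#' @export
run_sequential <- function(rows, variant = c("observed", "adjusted", "fe"),
                           covariates = "full") {
  variant <- match.arg(variant)
  stopifnot(all(c("pre_missed", "post_all") %in% names(rows)))
  d <- prepare_design(rows)
  d$pre_x_england <- d$pre_missed * d$england
  base <- c("pre_missed", "england", "pre_x_england")
  fit <- switch(variant,
    observed = fit_fe_lpm(d, did_formula("post_all", base, "none",
                                         time = character(0)),
                          fe = NULL, cluster = "hospital"),
    adjusted = fit_fe_lpm(d, did_formula("post_all", base, covariates),
                          fe = NULL, cluster = "hospital"),
    fe = fit_fe_lpm(d, did_formula("post_all", c("pre_missed", "pre_x_england"),
                                   covariates))
  )
  fit$effect_terms <- intersect(base, fit$coefficients$term)
  fit$variant <- variant
  fit
}
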