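---
title: "Evaluating all-or-nothing care-bundle incentives: model, generator, and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating all-or-nothing care-bundle incentives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`carebundles` studies pay-for-performance schemes in which a hospital earns a
single bonus per patient only when an entire bundle of care processes is
delivered, in the setting of the English Best Practice Tariff (BPT) for
fragility hip fracture (bonus from April 2010: £445, rising to £890 in
2011/12 and £1335 from 2012/13; Wales, with capitation payment and no bonus,
serves as the comparison system). The package has three layers: a theory
model of provider incentives under bundled versus itemized payment; a
calibrated synthetic generator of patient-level audit records; and a
policy-evaluation pipeline built on a fixed-effects linear probability model
with cluster-robust inference. This vignette records the modelling choices,
their defaults, and what the package's simulations can and cannot show.

## 1. Provider incentives under bundled payment

A provider can deliver two extra care processes with costs `c1`, `c2` and a
cost synergy `s ≥ 0`, so the joint cost is `c12 = c1 + c2 − s`. Under a
bundled price `P` (paid only when both are delivered) the provider delivers
both iff `P > c1 + c2 − s`; partial provision is never financially
attractive. Under itemized prices `p1`, `p2` the profit-maximising choice
partitions the cost plane into *none / only1 / only2 / both* regions, e.g.
process 1 alone iff `c1 < p1` and `c2 > p2 + s`. Holding funder generosity
fixed (`P = p1 + p2`), the comparison regions are:

* **A, B** — deliver one process under itemized payment but *both* under
  bundling (the bundle expands care);
* **C, D** — deliver one process under itemized payment but *nothing* under
  bundling (the bundle suppresses care);
* unchanged corners `both_both`, `none_none`.

All decision inequalities are strict; exact ties (measure zero under the
continuous cost densities) resolve to the lower-effort option, and
`classify_region()` labels boundary points `degenerate` rather than
assigning them arbitrarily, which keeps the partition property testable.

`simulate_providers()` aggregates choices, region shares, funder spending
(`P` per bundled deliverer; `p1`/`p2` per itemized process) and mean patient
benefit (`b12` for joint delivery, else `b1`/`b2`) over a provider cost
density — independent uniform or shifted lognormal marginals, optionally
coupled by a Gaussian copula. For uniform supports,
`region_areas_uniform()` computes the same quantities exactly by piecewise
quadrature of the polygonal regions; the Monte Carlo and analytic routes are
cross-checked in the test suite at one million draws. A useful exact case:
with costs uniform on the unit square, `p1 = p2 = 0.5` and `s = 0`, the
masses of A and C (and B and D) balance by symmetry, so spending is
identical under the two schemes and total benefit is identical precisely
when benefits are additive (`b12 = b1 + b2`); super-additive benefits
strictly favour bundling.

## 2. What the synthetic cohort emulates

The generator produces patient-level records shaped like a national
hip-fracture audit: hospital membership in an England/Wales panel, monthly
admission dates April 2008–March 2015 (financial years April–March),
categorical case-mix covariates, and eight binary care-process indicators
(BPT1–BPT4, BPT6–BPT9; the post-operative cognitive assessment BPT5 was not
collected for most of the window and is excluded throughout).

**Calibration.** Per-criterion achievement probabilities come from the
packaged country × financial-year table (`bpt_calibration()`). The *bundle*
row of that table is a joint probability over the era's criterion set —
seven criteria before April 2012, eight (adding BPT4) thereafter — and joint
behaviour is not determined by the marginals alone. The generator therefore
models the indicators as thresholded latent Gaussians and solves, per
country-year, for the exchangeable latent correlation at which the joint
achievement of the era set equals the calibrated bundle cell
(`calibrate_bundle_correlation()`, one-dimensional root finding on a
single-factor quadrature). The correlation is searched in `[0, 0.995]`; a
target below the independence product or above the comonotone bound clamps
at the nearest endpoint (two Welsh post-policy cells clamp, with residuals
below one percentage point). A latent-threshold/copula mechanism is the only
standard construction that hits arbitrary Bernoulli marginals while leaving
the dependence free, which is exactly the degree of freedom the bundle row
pins down.

**Clustering.** A share `hospital_icc` (default 0.05) of latent variance is
a persistent hospital intercept, drawn once per hospital, inducing
within-hospital correlation of achievement across patients, criteria and
years — the reason hospital-clustered standard errors are needed downstream.
The marginal calibration is preserved exactly because total latent variance
is held at one.

**Panel and cluster sizes.** Hospital counts grow linearly between the
configured start and end values (defaults 105→165 in England, 5→13 in
Wales), with hospitals joining and then staying. Patients per hospital-year
are negative binomial (defaults: mean 320 England, 270 Wales, size 8) —
overdispersed cluster sizes being the realistic default — unless
`patients_per_year` fixes country-year totals, which are then spread evenly
across that year's hospitals.

**Covariates and missingness.** Age band, sex, admission source, ASA grade,
pre-fracture mobility and fracture type are drawn independently from
per-country marginals; the published descriptives report these
distributions except age-band frequencies, for which the package ships a
synthetic distribution matching the published mean age (~82.5 years; file
`age_bands_synthetic.csv`). Missingness is patient-level and completely at
random at country rates (defaults 0.175 England, 0.188 Wales), masking only
admission source, ASA and mobility — the fields an audit records as
"unknown" — while age, sex and fracture type are always present (which is
why the limited-case-mix sensitivity keeps the full sample). Criterion
indicators are never masked: an unrecorded process is coded as not achieved.

**Injected effects.** For parameter-recovery experiments,
`cohort_config(effect = list(bundle = δ))` forces the full criterion set to
1 for England post-policy patients with probability `δ / (1 − p0_year)`,
where `p0_year` is the calibrated joint probability — a mixture that raises
the bundle probability by *exactly* `δ` in every post year, so δ is the true
ATT by construction. Per-criterion injections and a conditional-effort
injection for the sequential analysis work the same way.

**What the generator does not emulate.** Outcomes (mortality, length of
stay), non-random missingness, seasonality of admissions (dates are uniform
within year; the month dummies in the estimators are retained for
specification parity), case-mix differences between countries or over time,
and any real hospital identity. Passing tests therefore demonstrate
correctness of the estimators and the internal consistency of the
calibration — not that the design would be unconfounded in real data.

## 3. Estimation

`fit_fe_lpm()` is the shared core: least squares on within-hospital demeaned
data (the hospital intercepts are absorbed, never materialised), with the
cluster sandwich `B (Σ_g s_g s_g') B` assembled hospital by hospital.
Defaults and conventions:

* **CR1 small-sample factor** `G/(G−1) · (N−1)/(N−K)`, with `K` counting
  regression columns plus absorbed intercepts; CR0 available.
* **p-values** from `t(G−1)` — the conservative convention when one arm has
  few clusters (Wales has 5–13 hospitals).
* **Collinearity is an error, not a silent drop**: the country main effect
  is a linear combination of hospital effects, and the post indicator of the
  year dummies, so the DID specifications include only the interaction terms
  — matching the identifiable parameterisation — and any accidentally
  collinear column is reported by name.
* Singleton hospitals are retained (they add no within variation; their
  count is reported in `glance()`).

The pipeline implements: the average DID (England × post, year and calendar
month dummies, case-mix dummies with fixed reference categories, hospital
FE); period-specific effects for the three bonus eras; per-criterion and
criteria-count effects; sensitivity variants (balanced panel of hospitals
with ≥30 patients in every year, limited case-mix, seven-criterion bundle
definition, exclusion of the October 2009–March 2010 anticipation window);
and the sequential decision-making model (post-surgery achievement on
pre-surgery failure, country, and their interaction, in raw, adjusted and
hospital-FE variants).

**Pre-trend test.** Using pre-policy admissions only, quarter dummies (eight
quarters, first as reference) are interacted with the country indicator.
Calendar-month dummies are omitted here: over a two-year window month and
quarter indicators are exactly collinear (e.g. the two July–September
quarters sum to the July, August and September month indicators), so the
quarter terms already absorb season-by-year variation. The headline
decision statistic is the *summed deviation* `Σ τ_k` with its cluster-robust
t test — reported both over all seven interactions and excluding the final
(anticipation) quarter. A seven-dimensional cluster-robust Wald statistic is
also emitted, with a caveat: its covariance is effectively estimated from
the handful of control-country clusters, making it near-singular and badly
oversized in this design (the test suite documents ~50% rejection under the
null, against 9% for the summed-deviation test and ~5% for the same Wald
machinery in a well-conditioned design with many clusters and few
restrictions). Interpreting the joint row as a linear combination also
matches how such rows are conventionally reported with a standard error.

## 4. Problem sizes and numerical choices

The package's own verification uses: a ~30,000-patient calibrated
reproduction cohort (`reproduction_config()`: constant 165 + 13 hospital
panel, 3600/700 patients per country-year — the panel is held constant
because growing it under fixed yearly totals shrinks incumbents' post-period
weight and attenuates the two-way-FE average of time-growing effects, an
artifact of fixing totals rather than a feature of an audit whose volume
grew); 200 replicate cohorts of ~10,000 patients for CI coverage of an
injected 0.30 effect; 500 replicate two-year cohorts for the size of the
pre-trend test; and one million draws for the theory Monte Carlo against the
closed-form areas. Quadratures use `stats::integrate` at `rel.tol ≤ 1e-10`;
the region-area integrands are piecewise linear and are split at their
breakpoints, so adaptive quadrature is exact to tolerance. Root finding for
the bundle correlation uses `uniroot` at `tol = 1e-9` with memoisation
across repeated configurations.

## 5. Known limitations

* Two Welsh bundle cells are outside the range attainable under
  non-negative exchangeable dependence and clamp at independence
  (residual < 1 pp); matching them exactly would require negative
  dependence among criteria.
* The latent correlation is exchangeable within country-year; published
  post-policy correlation shifts between specific criterion pairs (e.g.
  geriatrician-related pairs) can be emulated by passing a scalar
  `criterion_rho`, but a full per-pair correlation matrix is configuration
  the package does not calibrate from printed data.
* The linear probability model is used throughout by design (marginal
  effects are the estimand); fitted probabilities outside `[0, 1]` are
  possible and no logit/probit alternative is provided.
* Cluster-robust inference with very few treated-or-control clusters is
  approximate; the package reports `n_clusters` with every fit and defaults
  to conservative `t(G−1)` reference distributions, but does not implement
  wild-cluster bootstrap.
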