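#' Payment scheme for the provider decision model
#'
#' Describes how the funder pays for two additional care processes: either a
#' single bundled price `P` paid only when both processes are delivered, or
#' itemized prices `p1`, `p2` paid per process delivered.  Prices must exceed
#' the minimum provider costs `k1`, `k2` (the support lower bounds of the cost
#' distribution), otherwise no provider could ever respond.
#'
#' @param mode `"bundled"` or `"itemized"`.
#' @param P Bundled price (required when `mode = "bundled"`); must exceed
#'   `k1 + k2`.
#' @param p1,p2 Per-process prices (required when `mode = "itemized"`); must
#'   exceed `k1` and `k2` respectively.
#' @param k1,k2 Lower bounds of the cost support (default 0).
#' @return A list of class `"payment_scheme"`.
#' @examples
#' payment_scheme("bundled", P = 1)
#' payment_scheme("itemized", p1 = 0.5, p2 = 1)
#' @export
payment_scheme <- function(mode = c("bundled", "itemized"), P = NULL,
                           p1 = NULL, p2 = NULL, k1 = 0, k2 = 0) {
  mode <- match.arg(mode)
  if (mode == "bundled") {
    if (is.null(P)) abort("bundled mode requires a price `P`")
    if (P <= k1 + k2) abort("bundled price must satisfy P > k1 + k2")
  } else {
    if (is.null(p1) || is.null(p2)) abort("itemized mode requires prices `p1` and `p2`")
    if (p1 <= k1 || p2 <= k2) abort("itemized prices must satisfy p1 > k1 and p2 > k2")
  }
  structure(list(mode = mode, P = P, p1 = p1, p2 = p2, k1 = k1, k2 = k2),
            class = "payment_scheme")
}

check_costs <- function(costs) {
  costs <- dplyr::as_tibble(costs)
  stopifnot(all(c("c1", "c2") %in% names(costs)))
  if (!"s" %in% names(costs)) costs$s <- 0
  if (any(costs$s < 0)) abort("cost synergy `s` must be non-negative")
  costs
}

#' Provider decision under a bundled payment
#'
#' A provider receives `P` only when both processes are delivered, so the
#' feasible choices are `both` and `none`.  With joint cost
#' `c12 = c1 + c2 - s`, the provider delivers both iff the bundle is strictly
#' profitable, `P > c1 + c2 - s`.  Ties (zero profit) resolve to `none`: all
#' decision inequalities in the model are strict.
#'
#' @param costs Data frame with columns `c1`, `c2` and optionally `s`
#'   (cost synergy, default 0).
#' @param scheme A bundled [payment_scheme()].
#' @return The input tibble with columns `pi_1`, `pi_2`, `pi_12` (profit from
#'   providing process 1 only, 2 only, or both) and `choice`
#'   (`"none"`/`"both"`).
#' @examples
#' decide_bundled(data.frame(c1 = 0.4, c2 = 0.5, s = 0.2),
#'                payment_scheme("bundled", P = 0.8))
#' @export
decide_bundled <- function(costs, scheme) {
  stopifnot(inherits(scheme, "payment_scheme"))
  if (scheme$mode != "bundled") abort("`scheme` must be a bundled payment scheme")
  costs <- check_costs(costs)
  costs |>
    dplyr::mutate(
      pi_1 = -.data$c1,
      pi_2 = -.data$c2,
      pi_12 = scheme$P - (.data$c1 + .data$c2 - .data$s),
      choice = factor(ifelse(.data$pi_12 > 0, "both", "none"),
                      levels = c("none", "only1", "only2", "both"))
    )
}

#' Provider decision under itemized (non-bundled) payment
#'
#' Each process is paid separately (`p1`, `p2`).  The provider picks the
#' profit-maximising option: process 1 alone when `c1 < p1` and `c2 > p2 + s`;
#' process 2 alone when `c2 < p2` and `c1 > p1 + s`; both when
#' `c1 < p1 + s`, `c2 < p2 + s` and the joint profit
#' `p1 + p2 - c1 - c2 + s` is positive; otherwise nothing.  Boundary ties
#' resolve to the lower-effort option.
#'
#' @inheritParams decide_bundled
#' @param scheme An itemized [payment_scheme()].
#' @return The input tibble with profit columns and `choice` in
#'   `none`/`only1`/`only2`/`both`.
#' @examples
#' decide_itemized(data.frame(c1 = 0.3, c2 = 2, s = 0.1),
#'                 payment_scheme("itemized", p1 = 0.5, p2 = 1))
#' @export
decide_itemized <- function(costs, scheme) {
  stopifnot(inherits(scheme, "payment_scheme"))
  if (scheme$mode != "itemized") abort("`scheme` must be an itemized payment scheme")
  costs <- check_costs(costs)
  p1 <- scheme$p1; p2 <- scheme$p2
  costs |>
    dplyr::mutate(
      pi_1 = p1 - .data$c1,
      pi_2 = p2 - .data$c2,
      pi_12 = p1 + p2 - .data$c1 - .data$c2 + .data$s,
      choice = dplyr::case_when(
        .data$c1 < p1 + .data$s & .data$c2 < p2 + .data$s & .data$pi_12 > 0 ~ "both",
        .data$c1 < p1 & .data$c2 > p2 + .data$s ~ "only1",
        .data$c2 < p2 & .data$c1 > p1 + .data$s ~ "only2",
        .default = "none"
      ),
      choice = factor(.data$choice, levels = c("none", "only1", "only2", "both"))
    )
}

#' Classify providers into bundled-vs-itemized comparison regions
#'
#' Compares decisions under itemized prices `(p1, p2)` with decisions under a
#' bundled price `P = p1 + p2` (so total funder generosity is held fixed).
#' Regions `A`/`B` collect providers that deliver only one process under
#' itemized payment but both under bundling; `C`/`D` those that deliver one
#' process under itemized payment but nothing under bundling; `both_both` and
#' `none_none` are the unchanged corners.  Cost points lying exactly on a
#' decision boundary are labelled `degenerate` rather than assigned
#' arbitrarily.
#'
#' @inheritParams decide_bundled
#' @param p1,p2 Itemized prices; the bundled price is `p1 + p2`.
#' @return Input tibble with a `region` factor column.
#' @examples
#' classify_region(data.frame(c1 = 0.3, c2 = 1.05, s = 0), p1 = 0.5, p2 = 1)
#' @export
classify_region <- function(costs, p1, p2) {
  costs <- check_costs(costs)
  it <- decide_itemized(costs, payment_scheme("itemized", p1 = p1, p2 = p2))
  bu <- decide_bundled(costs, payment_scheme("bundled", P = p1 + p2))
  on_boundary <- with(costs,
    c1 == p1 | c1 == p1 + s | c2 == p2 | c2 == p2 + s |
      (c1 + c2 - s) == (p1 + p2))
  lab <- dplyr::case_when(
    on_boundary ~ "degenerate",
    it$choice == "only1" & bu$choice == "both" ~ "A",
    it$choice == "only2" & bu$choice == "both" ~ "B",
    it$choice == "only1" & bu$choice == "none" ~ "C",
    it$choice == "only2" & bu$choice == "none" ~ "D",
    it$choice == "both" & bu$choice == "both" ~ "both_both",
    it$choice == "none" & bu$choice == "none" ~ "none_none",
    .default = "degenerate"
  )
  costs$region <- factor(lab, levels = c("A", "B", "C", "D", "both_both",
                                         "none_none", "degenerate"))
  costs
}

#' Cost distribution across providers
#'
#' Families: `"uniform"` — independent `U(min, max)` on each cost (optionally
#' coupled through a Gaussian copula with correlation `rho`); `"lognormal"` —
#' shifted lognormal `k + LN(meanlog, sdlog)` (same optional copula).  The
#' shift `k1`/`k2` is the support lower bound of the model.
#'
#' @param family `"uniform"` or `"lognormal"`.
#' @param min,max Uniform bounds (uniform family).
#' @param meanlog,sdlog Lognormal parameters (lognormal family).
#' @param k1,k2 Support lower bounds added to the draws (default 0).
#' @param rho Gaussian-copula correlation between the two costs (default 0).
#' @return A list of class `"cost_density"`.
#' @export
cost_density <- function(family = c("uniform", "lognormal"), min = 0, max = 1,
                         meanlog = 0, sdlog = 0.5, k1 = 0, k2 = 0, rho = 0) {
  family <- match.arg(family)
  stopifnot(abs(rho) < 1)
  structure(list(family = family, min = min, max = max, meanlog = meanlog,
                 sdlog = sdlog, k1 = k1, k2 = k2, rho = rho),
            class = "cost_density")
}

draw_costs <- function(density, n) {
  stopifnot(inherits(density, "cost_density"))
  if (density$rho != 0) {
    z1 <- rnorm(n)
    z2 <- density$rho * z1 + sqrt(1 - density$rho^2) * rnorm(n)
    u1 <- pnorm(z1); u2 <- pnorm(z2)
  } else {
    u1 <- runif(n); u2 <- runif(n)
  }
  q <- switch(density$family,
    uniform = function(u) qunif(u, density$min, density$max),
    lognormal = function(u) qlnorm(u, density$meanlog, density$sdlog)
  )
  tibble::tibble(c1 = density$k1 + q(u1), c2 = density$k2 + q(u2))
}

#' Monte Carlo comparison of bundled and itemized payment
#'
#' Draws `n` providers from a cost distribution, lets each choose under a
#' bundled price `P` (default `p1 + p2`) and under itemized prices
#' `(p1, p2)`, and aggregates choice shares, comparison-region shares, funder
#' spending per provider, and mean patient benefit per provider.  Spending is
#' `P` per bundled provider delivering both, and `p1`/`p2` per process under
#' itemized payment.  Benefit is `b12` when both processes are delivered,
#' `b1`/`b2` for a single process, 0 otherwise.
#'
#' @param n Number of providers to draw.
#' @param density A [cost_density()].
#' @param p1,p2 Itemized prices.
#' @param s Cost synergy (scalar, applied to all providers).
#' @param P Bundled price; defaults to `p1 + p2`.
#' @param benefit Numeric vector `c(b1, b2, b12)` of patient benefits.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A list of class `"scheme_comparison"` with tibbles `shares`
#'   (per-scheme choice shares), `regions` (comparison-region shares) and
#'   `welfare` (per-scheme spending and benefit per provider), plus the inputs
#'   and seed as metadata.
#' @examples
#' simulate_providers(10000, cost_density("uniform"), p1 = 0.5, p2 = 0.5,
#'                    s = 0, seed = 1)
#' @export
simulate_providers <- function(n, density, p1, p2, s = 0, P = p1 + p2,
                               benefit = c(b1 = 1, b2 = 1, b12 = 2),
                               seed = 1) {
  stopifnot(n >= 1, s >= 0)
  set.seed(seed)
  costs <- draw_costs(density, n)
  costs$s <- s
  bu <- decide_bundled(costs, payment_scheme("bundled", P = P,
                                             k1 = density$k1, k2 = density$k2))
  it <- decide_itemized(costs, payment_scheme("itemized", p1 = p1, p2 = p2,
                                              k1 = density$k1, k2 = density$k2))
  reg <- classify_region(costs, p1, p2)

  share_tab <- function(choice, scheme) {
    counts <- as.numeric(table(choice))
    tibble::tibble(scheme = scheme,
                   choice = factor(levels(choice), levels(choice)),
                   share = counts / n)
  }
  shares <- dplyr::bind_rows(share_tab(bu$choice, "bundled"),
                             share_tab(it$choice, "itemized"))
  regions <- tibble::tibble(
    region = factor(levels(reg$region), levels(reg$region)),
    share = as.numeric(table(reg$region)) / n
  )
  b <- setNames(as.numeric(benefit), c("b1", "b2", "b12"))
  ben_of <- function(choice) {
    c(none = 0, only1 = b[["b1"]], only2 = b[["b2"]], both = b[["b12"]])[as.character(choice)]
  }
  welfare <- tibble::tibble(
    scheme = c("bundled", "itemized"),
    spending = c(mean(P * (bu$choice == "both")),
                 mean(p1 * (it$choice %in% c("only1", "both")) +
                        p2 * (it$choice %in% c("only2", "both")))),
    benefit = c(mean(ben_of(bu$choice)), mean(ben_of(it$choice)))
  )
  structure(list(shares = shares, regions = regions, welfare = welfare,
                 n = n, p1 = p1, p2 = p2, s = s, P = P,
                 benefit = b, density = density, seed = seed),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("Bundled vs itemized payment comparison (n =", x$n, "providers)\n")
  cat(sprintf("p1 = %g, p2 = %g, s = %g, P = %g\n", x$p1, x$p2, x$s, x$P))
  print(tidyr::pivot_wider(x$shares, names_from = "scheme", values_from = "share"))
  print(x$welfare)
  invisible(x)
}

# Integrate, over c1 in [lo, hi], the length of a c2 interval whose bounds are
# piecewise-linear in c1.  `interval(c1)` returns cbind(lower, upper); the
# integrand is piecewise linear, so adaptive quadrature split at the supplied
# breakpoints is exact to tolerance.
integrate_region <- function(interval, lo, hi, breaks) {
  breaks <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  f <- function(c1) {
    iv <- interval(c1)
    pmax(pmin(iv[, 2], hi) - pmax(iv[, 1], lo), 0)
  }
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    total <- total + integrate(f, breaks[i], breaks[i + 1],
                               rel.tol = 1e-12, abs.tol = 1e-12)$value
  }
  total
}

#' Exact region probabilities under independent uniform costs
#'
#' Computes, by piecewise quadrature of the half-plane partition (exact for
#' the polygonal regions involved), the probability mass of every provider
#' choice and comparison region when `c1`, `c2` are independent
#' `U(lower, upper)`.  Serves as the closed-form oracle for
#' [simulate_providers()].
#'
#' @param p1,p2 Itemized prices.
#' @param s Cost synergy.
#' @param lower,upper Bounds of the uniform cost support.
#' @param P Bundled price (default `p1 + p2`).
#' @return A tibble with columns `quantity` (`bundled_both`, `itemized_none`,
#'   `itemized_only1`, `itemized_only2`, `itemized_both`, `region_A` ...
#'   `region_D`) and `share` (probability under the uniform density).
#' @examples
#' region_areas_uniform(p1 = 0.5, p2 = 0.5, s = 0)
#' @export
region_areas_uniform <- function(p1, p2, s = 0, lower = 0, upper = 1,
                                 P = p1 + p2) {
  stopifnot(s >= 0, upper > lower)
  lo <- lower; hi <- upper
  area <- (hi - lo)^2
  brk <- c(p1, p1 + s, p2, p2 + s, P + s - hi, P + s - lo,
           p1 + p2 + s - hi, p1 + p2 + s - lo, P - p2, P + s - p2)

  bundled_both <- integrate_region(function(c1) cbind(lo, P + s - c1), lo, hi, brk)
  it_both <- integrate_region(function(c1)
    cbind(lo, ifelse(c1 < p1 + s, pmin(p2 + s, p1 + p2 + s - c1), lo)),
    lo, hi, brk)
  it_only1 <- integrate_region(function(c1)
    cbind(ifelse(c1 < p1, p2 + s, hi), hi), lo, hi, brk)
  it_only2 <- integrate_region(function(c1)
    cbind(ifelse(c1 > p1 + s, lo, hi), ifelse(c1 > p1 + s, p2, hi)), lo, hi, brk)
  reg_A <- integrate_region(function(c1)
    cbind(ifelse(c1 < p1, p2 + s, hi), ifelse(c1 < p1, P + s - c1, hi)), lo, hi, brk)
  reg_B <- integrate_region(function(c1)
    cbind(ifelse(c1 > p1 + s, lo, hi), ifelse(c1 > p1 + s, pmin(p2, P + s - c1), lo)),
    lo, hi, brk)
  reg_C <- it_only1 - reg_A
  reg_D <- it_only2 - reg_B

  tibble::tibble(
    quantity = c("bundled_both", "bundled_none", "itemized_none",
                 "itemized_only1", "itemized_only2", "itemized_both",
                 "region_A", "region_B", "region_C", "region_D"),
    share = c(bundled_both, area - bundled_both,
              area - it_only1 - it_only2 - it_both,
              it_only1, it_only2, it_both,
              reg_A, reg_B, reg_C, reg_D) / area
  )
}

#' Analytic welfare comparison under independent uniform costs
#'
#' Uses [region_areas_uniform()] to compute exact funder spending and mean
#' patient benefit per provider under a bundled price `P = p1 + p2` and under
#' itemized prices, without Monte Carlo error.  Used for the welfare
#' equivalence result: when the comparison regions balance (mass of A equals
#' C and B equals D) spending is identical under the two schemes, and benefit
#' is identical iff benefits are additive (`b12 = b1 + b2`).
#'
#' @inheritParams region_areas_uniform
#' @param benefit Numeric vector `c(b1, b2, b12)`.
#' @return A tibble with one row per scheme: `spending`, `benefit`.
#' @export
compare_schemes_uniform <- function(p1, p2, s = 0, lower = 0, upper = 1,
                                    benefit = c(b1 = 1, b2 = 1, b12 = 2),
                                    P = p1 + p2) {
  a <- region_areas_uniform(p1, p2, s, lower, upper, P)
  g <- function(q) a$share[a$quantity == q]
  b <- setNames(as.numeric(benefit), c("b1", "b2", "b12"))
  tibble::tibble(
    scheme = c("bundled", "itemized"),
    spending = c(P * g("bundled_both"),
                 p1 * (g("itemized_only1") + g("itemized_both")) +
                   p2 * (g("itemized_only2") + g("itemized_both"))),
    benefit = c(b[["b12"]] * g("bundled_both"),
                b[["b1"]] * g("itemized_only1") + b[["b2"]] * g("itemized_only2") +
                  b[["b12"]] * g("itemized_both"))
  )
}
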