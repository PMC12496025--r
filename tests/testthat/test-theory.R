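test_that("bundled decision follows the strict profitability inequality", {
  sch <- payment_scheme("bundled", P = 0.8)
  d <- decide_bundled(data.frame(c1 = 0.4, c2 = 0.5, s = 0.2), sch)
  expect_equal(as.character(d$choice), "both")
  expect_equal(d$pi_12, 0.1)
  expect_equal(d$pi_1, -0.4)

  d2 <- decide_bundled(data.frame(c1 = 1, c2 = 1, s = 0),
                       payment_scheme("bundled", P = 1.5))
  expect_equal(as.character(d2$choice), "none")

  # zero-profit boundary resolves to none (strict inequality)
  d3 <- decide_bundled(data.frame(c1 = 0.5, c2 = 0.5, s = 0),
                       payment_scheme("bundled", P = 1))
  expect_equal(as.character(d3$choice), "none")

  expect_error(decide_bundled(data.frame(c1 = 1, c2 = 1, s = -0.1), sch),
               "non-negative")
  expect_error(payment_scheme("bundled", P = 0.5, k1 = 0.3, k2 = 0.3),
               "k1 \\+ k2")
})

test_that("itemized decision picks the profit-maximising option", {
  sch <- payment_scheme("itemized", p1 = 0.5, p2 = 1)
  cases <- data.frame(c1 = c(0.3, 0.4, 5), c2 = c(2, 0.9, 5),
                      s = c(0.1, 0.1, 0))
  d <- decide_itemized(cases, sch)
  expect_equal(as.character(d$choice), c("only1", "both", "none"))
  expect_equal(d$pi_12[2], 0.3)
  # symmetric case for only2
  d2 <- decide_itemized(data.frame(c1 = 2, c2 = 0.3, s = 0.1),
                        payment_scheme("itemized", p1 = 1, p2 = 0.5))
  expect_equal(as.character(d2$choice), "only2")
})

test_that("region classification agrees with the two deciders and flags boundaries", {
  d <- classify_region(data.frame(c1 = c(0.3, 0.3, 0.1, 0.5),
                                  c2 = c(1.05, 2, 0.1, 0.4), s = 0),
                       p1 = 0.5, p2 = 1)
  expect_equal(as.character(d$region), c("A", "C", "both_both", "degenerate"))

  # cross-tabulation oracle on random draws: region labels must match the
  # choices implied by the two payment schemes
  set.seed(42)
  costs <- data.frame(c1 = runif(4000, 0, 2), c2 = runif(4000, 0, 2), s = 0.2)
  reg <- classify_region(costs, p1 = 0.6, p2 = 0.9)
  it <- decide_itemized(costs, payment_scheme("itemized", p1 = 0.6, p2 = 0.9))
  bu <- decide_bundled(costs, payment_scheme("bundled", P = 1.5))
  expect_equal(reg$region == "A", it$choice == "only1" & bu$choice == "both")
  expect_equal(reg$region == "D", it$choice == "only2" & bu$choice == "none")
  # partition: every off-boundary point gets exactly one label per scheme
  expect_false(any(reg$region == "degenerate"))
})

test_that("uniform region areas match frozen closed-form values", {
  a <- region_areas_uniform(p1 = 0.5, p2 = 0.5, s = 0, P = 1)
  g <- function(tab, q) tab$share[tab$quantity == q]
  expect_equal(g(a, "bundled_both"), 0.5, tolerance = 1e-9)
  expect_equal(g(a, "itemized_both"), 0.25, tolerance = 1e-9)
  # synergy widens both regions: area of {c1<0.7, c2<0.7, c1+c2<1.2}
  a2 <- region_areas_uniform(p1 = 0.5, p2 = 0.5, s = 0.2, P = 1)
  expect_equal(g(a2, "itemized_both"), 0.47, tolerance = 1e-9)
  expect_equal(g(a2, "bundled_both"), 1 - 0.8^2 / 2, tolerance = 1e-9)
  # P = 1, s = 0.25: area of {c1 + c2 < 1.25} in the unit square
  a3 <- region_areas_uniform(p1 = 0.5, p2 = 0.5, s = 0.25, P = 1)
  expect_equal(g(a3, "bundled_both"), 0.71875, tolerance = 1e-9)
  # shares of each partition sum to one
  expect_equal(g(a, "itemized_none") + g(a, "itemized_only1") +
                 g(a, "itemized_only2") + g(a, "itemized_both"), 1,
               tolerance = 1e-9)
  expect_equal(sum(a$share[grepl("region", a$quantity)]) +
                 g(a, "itemized_both") + g(a, "itemized_none") -
                 g(a, "bundled_both") - g(a, "bundled_none"), 0,
               tolerance = 1e-6)
})

test_that("Monte Carlo shares agree with the analytic oracle and sum to 1", {
  n <- 50000
  sc <- simulate_providers(n, cost_density("uniform"), p1 = 0.4, p2 = 0.7,
                           s = 0.15, seed = 11)
  a <- region_areas_uniform(p1 = 0.4, p2 = 0.7, s = 0.15)
  g <- function(q) a$share[a$quantity == q]
  for (sch in c("bundled", "itemized")) {
    expect_equal(sum(sc$shares$share[sc$shares$scheme == sch]), 1)
  }
  chk <- list(c("itemized", "both", "itemized_both"),
              c("itemized", "only1", "itemized_only1"),
              c("bundled", "both", "bundled_both"))
  for (x in chk) {
    mc <- sc$shares$share[sc$shares$scheme == x[1] & sc$shares$choice == x[2]]
    p <- g(x[3])
    expect_lt(abs(mc - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  for (r in c("A", "B", "C", "D")) {
    mc <- sc$regions$share[sc$regions$region == r]
    p <- g(paste0("region_", r))
    expect_lt(abs(mc - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("itemized-both providers always choose both under the bundled price", {
  set.seed(9)
  viol <- 0
  for (i in 1:20) {
    p1 <- runif(1, 0.1, 2); p2 <- runif(1, 0.1, 2); s <- runif(1, 0, 0.5)
    costs <- data.frame(c1 = runif(2000, 0, 3), c2 = runif(2000, 0, 3), s = s)
    it <- decide_itemized(costs, payment_scheme("itemized", p1 = p1, p2 = p2))
    bu <- decide_bundled(costs, payment_scheme("bundled", P = p1 + p2))
    viol <- viol + sum(it$choice == "both" & bu$choice != "both")
  }
  expect_equal(viol, 0)
})

test_that("bundled both-share is monotone in the price and in the synergy", {
  shares_P <- vapply(seq(0.6, 1.6, by = 0.2), function(P) {
    a <- region_areas_uniform(p1 = 0.5, p2 = 0.5, s = 0.1, P = P)
    a$share[a$quantity == "bundled_both"]
  }, numeric(1))
  expect_true(all(diff(shares_P) >= 0))
  shares_s <- vapply(seq(0, 0.5, by = 0.1), function(s) {
    a <- region_areas_uniform(p1 = 0.5, p2 = 0.5, s = s, P = 1)
    a$share[a$quantity == "bundled_both"]
  }, numeric(1))
  expect_true(all(diff(shares_s) >= 0))
})

test_that("welfare comparison: equal spending under balanced regions, benefit ranked by synergy", {
  # U(0,1)^2 with p1 = p2 = 0.5: region masses A = C and B = D by symmetry
  cmp_add <- compare_schemes_uniform(0.5, 0.5, s = 0,
                                     benefit = c(b1 = 1, b2 = 1, b12 = 2))
  expect_lt(abs(diff(cmp_add$spending)), 1e-6)
  expect_lt(abs(diff(cmp_add$benefit)), 1e-6)
  cmp_syn <- compare_schemes_uniform(0.5, 0.5, s = 0,
                                     benefit = c(b1 = 1, b2 = 1, b12 = 2.5))
  expect_lt(abs(diff(cmp_syn$spending)), 1e-6)
  expect_gt(cmp_syn$benefit[cmp_syn$scheme == "bundled"],
            cmp_syn$benefit[cmp_syn$scheme == "itemized"])
})

test_that("cost densities respect support lower bounds and the copula couples draws", {
  set.seed(3)
  d <- carebundles:::draw_costs(cost_density("lognormal", meanlog = -1,
                                             sdlog = 0.4, k1 = 0.2, k2 = 0.5), 2000)
  expect_true(all(d$c1 > 0.2) && all(d$c2 > 0.5))
  dc <- carebundles:::draw_costs(cost_density("uniform", rho = 0.8), 5000)
  expect_gt(cor(dc$c1, dc$c2), 0.6)
})
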