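# Probabilistic sensitivity analysis

test_that("method-of-moments beta and gamma match the spec'd closed forms", {
  expect_equal(moments_to_beta(0.9, 0.15), c(alpha = 2.7, beta = 0.3), tolerance = 1e-12)
  expect_equal(moments_to_gamma(6600, 0.2), c(shape = 25, scale = 264), tolerance = 1e-12)
})

test_that("method-of-moments parameters reproduce the requested moments", {
  set.seed(1)
  for (i in 1:20) {
    m <- runif(1, 0.05, 0.95)
    s <- runif(1, 0.01, 0.9 * sqrt(m * (1 - m)))
    ab <- moments_to_beta(m, s)
    expect_equal(unname(ab["alpha"] / sum(ab)), m, tolerance = 1e-10)
    v <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
    expect_equal(sqrt(v), s, tolerance = 1e-10)
    g <- moments_to_gamma(runif(1, 100, 50000), cv <- runif(1, 0.05, 1))
    expect_equal(unname(g["shape"] * g["scale"] / sqrt(g["shape"] * g["scale"]^2)),
                 1 / cv, tolerance = 1e-10)
  }
  expect_error(moments_to_beta(0.5, 0.6), "'sd'")
  expect_error(moments_to_gamma(-5, 0.2), "'mean'")
})

test_that("Wilson intervals reproduce the published CIs to one decimal", {
  round1 <- function(k) round(100 * wilson_interval(k, 1000), 1)
  expect_equal(unname(round1(586)), c(55.5, 61.6))
  expect_equal(unname(round1(538)), c(50.7, 56.9))
  expect_equal(unname(round1(367)), c(33.8, 39.7))
  # degenerate edges stay in [0, 1]
  expect_equal(unname(wilson_interval(0, 10)[1]), 0)
  expect_lt(wilson_interval(10, 10)[1], 1)
  expect_equal(unname(wilson_interval(10, 10)[2]), 1)
  expect_error(wilson_interval(11, 10), "'k'")
})

test_that("PSA is deterministic given the seed", {
  base <- markov_parameters()
  a <- run_psa(base, n_iter = 100, seed = 5)
  b <- run_psa(base, n_iter = 100, seed = 5)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(base, n_iter = 100, seed = 6)
  expect_false(identical(a$draws$delta_cost, c2$draws$delta_cost))
})

test_that("a point-mass PSA collapses to the deterministic model", {
  base <- markov_parameters()
  dists <- parameter_distributions(base, sd_recurrent = 0, cv_mortality = 0,
                                   sd_utility = 0, cv_cost = 0, rrr_sd = 0)
  psa <- run_psa(base, dists, n_iter = 20, seed = 1)
  inc <- incremental(base)
  expect_equal(unique(psa$draws$delta_cost), inc$delta_cost, tolerance = 1e-10)
  expect_equal(unique(psa$draws$delta_qaly), inc$delta_qaly, tolerance = 1e-10)
  s <- psa$summaries$delta_cost
  expect_equal(unname(s["p2.5"]), unname(s["p97.5"]))
  expect_true(all(psa$draws$icer == inc$icer))
})

test_that("CE probability is monotone in price, WTP, and RRR (common seed)", {
  ce <- function(base, w = 120000) {
    unname(run_psa(base, parameter_distributions(base), n_iter = 300, seed = 3,
                   wtps = w)$ce_probability[[as.character(w)]]["point"])
  }
  prices <- c(2000, 6600, 12000, 25000)
  p_ce <- vapply(prices, function(x) {
    ce(markov_parameters(price = price_schedule("p", x)))
  }, 0)
  expect_true(all(diff(p_ce) <= 0))

  base <- markov_parameters()
  by_wtp <- vapply(c(50000, 120000, 250000), function(w) ce(base, w), 0)
  expect_true(all(diff(by_wtp) >= 0))

  by_rrr <- vapply(c(0.1, 0.32, 0.6), function(r) {
    b <- markov_parameters(rrr = r)
    unname(run_psa(b, parameter_distributions(b, rrr_sd = 0.03), n_iter = 300,
                   seed = 3, wtps = 120000)$ce_probability[["120000"]]["point"])
  }, 0)
  expect_true(all(diff(by_rrr) >= 0))
})

test_that("reported summaries are pure functions of the persisted draws", {
  psa <- run_psa(markov_parameters(), n_iter = 200, seed = 8)
  d <- psa$draws
  expect_equal(unname(psa$summaries$delta_cost["median"]),
               unname(stats::quantile(d$delta_cost, 0.5, type = 7)), tolerance = 1e-12)
  expect_equal(unname(psa$summaries$delta_qaly["mean"]), mean(d$delta_qaly),
               tolerance = 1e-12)
  k <- sum(d$nmb_120000 > 0)
  expect_equal(unname(psa$ce_probability[["120000"]]["point"]), k / 200)
  expect_equal(unname(psa$ce_probability[["120000"]][c("lo", "hi")]),
               unname(wilson_interval(k, 200)))
})

test_that("invalid draws are redrawn and a high redraw rate warns", {
  base <- markov_parameters(p_recurrent_annual = 0.6,
                            p_mort_background_annual = 0.3)
  dists <- parameter_distributions(base, sd_recurrent = 0.15,
                                   cv_mortality = 0.3, rrr_sd = 0)
  set.seed(1)
  expect_warning(d <- icadcea:::draw_parameter_matrix(base, dists, 500),
                 "redraw rate")
  expect_true(all(d[, "p_recurrent_annual"] + d[, "p_mort_background_annual"] <= 1))
})

test_that("plane export carries one row per iteration with consistent flags", {
  psa <- run_psa(markov_parameters(), n_iter = 150, seed = 2)
  pl <- plane_export(psa)
  expect_identical(nrow(pl), 150L)
  expect_identical(pl$delta_qaly, psa$draws$delta_qaly)
  expect_identical(pl$ce_at_120000,
                   as.integer(120000 * pl$delta_qaly - pl$delta_cost > 0))
  expect_equal(mean(pl$ce_at_120000),
               unname(psa$ce_probability[["120000"]]["point"]))
})
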