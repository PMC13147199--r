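# Three-state Markov engine

test_that("rate-scale RRR matches the closed form", {
  expect_equal(icadcea:::treated_recurrence_prob(0.149, 0.32, "rate"),
               1 - 0.851^0.68, tolerance = 1e-12)
  expect_equal(1 - 0.851^0.68, 0.1039, tolerance = 1e-4)
  expect_equal(icadcea:::treated_recurrence_prob(0.149, 0.32, "probability"),
               0.149 * 0.68, tolerance = 1e-12)
  # rrr = 0 is the identity on both scales
  expect_equal(icadcea:::treated_recurrence_prob(0.3, 0, "rate"), 0.3)
})

test_that("transition matrices are row-stochastic with an absorbing death state", {
  for (arm in c("standard", "pcsk9i")) {
    m <- build_transition_matrix(markov_parameters(), arm)
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(m >= 0))
    expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  }
})

test_that("immortal full-utility cohort accrues exactly horizon QALYs", {
  p <- markov_parameters(p_recurrent_annual = 0, p_mort_background_annual = 0,
                         p_mort_poststroke_annual = 0, u_stable = 1,
                         u_recurrent = 1, discount_rate_annual = 0)
  for (arm in c("standard", "pcsk9i")) {
    expect_equal(run_cohort_model(p, arm)$total_qaly_discounted, 5, tolerance = 1e-12)
  }
})

test_that("drug cost reduces to a geometric series when nobody exits", {
  p <- markov_parameters(p_recurrent_annual = 0, p_mort_background_annual = 0,
                         p_mort_poststroke_annual = 0, discontinuation_annual = 0)
  trt <- run_cohort_model(p, "pcsk9i")
  expect_equal(trt$drug_cost_component, 6600 * sum(1.03^-(0:4)), tolerance = 1e-10)
  expect_equal(trt$care_cost_component, 0)
})

test_that("engine matches a scalar loop-based oracle on 50 random parameterizations", {
  set.seed(2024)
  for (rep in 1:50) {
    prec <- runif(1, 0.01, 0.4)
    pm <- runif(1, 0.005, min(0.2, 1 - prec - 0.01))
    par <- markov_parameters(
      p_recurrent_annual = prec,
      p_mort_background_annual = pm,
      p_mort_poststroke_annual = runif(1, 0.01, 0.5),
      u_stable = runif(1, 0.5, 1), u_recurrent = runif(1, 0.1, 0.5),
      discount_rate_annual = runif(1, 0, 0.08),
      discontinuation_annual = runif(1, 0, 0.3),
      rrr = runif(1, 0, 0.8),
      price = price_schedule("x", round(runif(5, 0, 20000))),
      c_stroke_state_annual = runif(1, 0, 60000),
      c_stroke_event_acute = runif(1, 0, 60000),
      drug_cost_basis = sample(c("alive", "on_treatment"), 1),
      effect_off_treatment = sample(c(TRUE, FALSE), 1)
    )
    arm <- sample(c("standard", "pcsk9i"), 1)
    res <- run_cohort_model(par, arm)
    expect_equal(unname(rowSums(res$occupancy_trace)), rep(1, 6), tolerance = 1e-10)

    # independent scalar recomputation
    treated <- arm == "pcsk9i"
    p_on <- if (treated) 1 - (1 - prec)^(1 - par$rrr) else prec
    p_off <- if (treated && par$effect_off_treatment) p_on else prec
    on <- if (treated) 1 else 0; off <- 1 - on; rec <- 0; dead <- 0
    q <- drug <- care <- 0
    for (k in 1:5) {
      inflow <- on * p_on + off * p_off
      new_on <- on * (1 - p_on - par$p_mort_background_annual) *
        (1 - par$discontinuation_annual)
      new_off <- on * (1 - p_on - par$p_mort_background_annual) *
        par$discontinuation_annual +
        off * (1 - p_off - par$p_mort_background_annual)
      new_rec <- inflow + rec * (1 - par$p_mort_poststroke_annual)
      new_dead <- dead + (on + off) * par$p_mort_background_annual +
        rec * par$p_mort_poststroke_annual
      on <- new_on; off <- new_off; rec <- new_rec; dead <- new_dead
      df <- (1 + par$discount_rate_annual)^(-(k - 1))
      q <- q + df * (par$u_stable * (on + off) + par$u_recurrent * rec)
      care <- care + df * (par$c_stroke_state_annual * rec +
                             par$c_stroke_event_acute * inflow)
      if (treated) {
        payers <- if (par$drug_cost_basis == "alive") on + off + rec else on
        drug <- drug + df * par$price$annual_cost_by_year[k] * payers
      }
    }
    expect_equal(res$total_qaly_discounted, q, tolerance = 1e-10)
    expect_equal(res$drug_cost_component, drug, tolerance = 1e-10)
    expect_equal(res$care_cost_component, care, tolerance = 1e-10)
  }
})

test_that("costs are linear in the cost parameters", {
  p1 <- markov_parameters()
  p2 <- markov_parameters(c_stroke_state_annual = 2 * p1$c_stroke_state_annual,
                          c_stroke_event_acute = 2 * p1$c_stroke_event_acute,
                          price = price_schedule("x2", 2 * 6600))
  r1 <- run_cohort_model(p1, "pcsk9i")
  r2 <- run_cohort_model(p2, "pcsk9i")
  expect_equal(r2$total_cost_discounted, 2 * r1$total_cost_discounted, tolerance = 1e-10)
})

test_that("incremental flags dominance, domination, and undefined ICERs", {
  free <- price_schedule("free", 0)
  expect_identical(incremental(markov_parameters(price = free))$flag, "dominant")
  harm <- markov_parameters(rrr = -0.5)
  expect_identical(incremental(harm)$flag, "dominated")
  null <- markov_parameters(rrr = 0, price = free, discontinuation_annual = 0)
  inc0 <- incremental(null)
  expect_identical(inc0$flag, "undefined")
  expect_true(is.na(inc0$icer))
  ok <- incremental(markov_parameters())
  expect_identical(ok$flag, "ok")
  expect_equal(ok$icer, ok$delta_cost / ok$delta_qaly)
})

test_that("base-case deterministic run is economically sensible", {
  inc <- incremental(markov_parameters())
  expect_gt(inc$delta_qaly, 0)
  expect_gt(inc$delta_cost, 0)
  expect_gt(inc$icer, 50000)
  expect_lt(inc$icer, 200000)
})

test_that("parameters round-trip through YAML", {
  p <- markov_parameters(rrr = 0.25, price = builtin_schedules()$dtc$inclisiran)
  path <- tempfile(fileext = ".yaml")
  write_markov_parameters(p, path)
  back <- read_markov_parameters(path)
  expect_equal(unclass(back), unclass(p))
  r1 <- incremental(p); r2 <- incremental(back)
  expect_identical(r1$icer, r2$icer)
})

test_that("parameter validation names the offending field", {
  expect_error(markov_parameters(p_recurrent_annual = 1.5), "'p_recurrent_annual'")
  expect_error(markov_parameters(rrr = 1.2), "'rrr'")
  expect_error(markov_parameters(u_dead = 0.1), "'u_dead'")
  expect_error(markov_parameters(price = 6600), "'price'")
  expect_error(markov_parameters(p_recurrent_annual = 0.9,
                                 p_mort_background_annual = 0.3),
               "exit probability")
  expect_error(price_schedule("bad", c(1, 2)), "'annual_cost_by_year'")
  expect_error(price_schedule("neg", -5), "'annual_cost_by_year'")
})
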