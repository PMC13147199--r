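# Evidence synthesis: Cox fit and predictive margins

make_fit <- function(n = 367L, seed = 1L, ...) {
  rec <- generate_cohort(cohort_spec(n = n, seed = seed, ...))
  list(rec = rec, fit = fit_cox(rec))
}

test_that("Cox fit matches a brute-force partial likelihood on a tiny dataset", {
  # three patients, two events, no ties: the Efron and Breslow partial
  # likelihoods coincide and can be maximized on a grid
  # the first event must not carry the largest covariate in its risk set,
  # otherwise the partial likelihood is monotone and the MLE diverges
  rec <- data.frame(id = 1:3, age_years = 60, sex = "male",
                    ldl_baseline = c(100, 150, 60), ldl_change_30d = 0,
                    event = c(1L, 1L, 0L), time_days = c(100, 200, 300))
  fit <- fit_cox(rec, covariate_names = character(0))
  x <- log(rec$ldl_baseline)
  logpl <- function(b) {
    # risk sets at the two event times: {1,2,3} then {2,3}
    (b * x[1] - log(sum(exp(b * x)))) + (b * x[2] - log(sum(exp(b * x[2:3]))))
  }
  grid <- seq(-10, 10, by = 1e-4)
  b_hat <- grid[which.max(vapply(grid, logpl, 0))]
  expect_equal(unname(fit$coefficients[1]), b_hat, tolerance = 1e-3)
})

test_that("Cox model recovers the generator's log hazard ratio at n = 10,000", {
  # follow-up extended and LDL dispersion widened for estimation precision
  # (design choice made a priori for statistical power, not a calibration)
  h <- make_fit(n = 10000L, seed = 1, followup_days_range = c(365, 1461),
                ldl_baseline_scale = 0.5)
  b <- unname(h$fit$coefficients["log(ldl_attained)"])
  expect_lt(abs(b - 0.58) / 0.58, 0.10)
})

test_that("null generator yields a near-zero LDL coefficient", {
  h <- make_fit(n = 10000L, seed = 2, log_hr_per_unit_log_ldl = 0,
                followup_days_range = c(365, 1461))
  b <- unname(h$fit$coefficients["log(ldl_attained)"])
  se <- sqrt(diag(h$fit$covariance))[1]
  expect_lt(abs(b), 3 * se)
})

test_that("predictive margins equal an explicit per-patient loop", {
  h <- make_fit()
  eff <- ldl_effect(0.60, 0.05)
  est <- project_margins(h$fit, h$rec, eff)

  cumhaz_1y <- h$fit$baseline_cumhaz(365.25)
  beta <- h$fit$coefficients
  rate_one <- function(row, ldl_att) {
    mm <- c(`log(ldl_attained)` = log(ldl_att),
            age_years = row$age_years,
            sexmale = as.numeric(row$sex == "male"))
    cumhaz_1y * exp(sum(beta[names(mm)] * mm))
  }
  rc <- rt <- numeric(nrow(h$rec))
  for (i in seq_len(nrow(h$rec))) {
    row <- h$rec[i, ]
    rc[i] <- rate_one(row, row$ldl_baseline + row$ldl_change_30d)
    rt[i] <- rate_one(row, row$ldl_baseline * (1 - 0.60))
  }
  expect_equal(est$rate_control, mean(rc), tolerance = 1e-10)
  expect_equal(est$rate_treated, mean(rt), tolerance = 1e-10)
  expect_equal(est$rrr, 1 - mean(rt) / mean(rc), tolerance = 1e-10)
})

test_that("zero LDL reduction on an unchanged cohort gives exactly zero RRR", {
  h <- make_fit()
  rec0 <- h$rec
  rec0$ldl_change_30d <- 0
  fit0 <- fit_cox(rec0)
  est <- project_margins(fit0, rec0, ldl_effect(0, 0))
  expect_identical(est$rrr, 0)
})

test_that("projected RRR is monotone in the LDL reduction", {
  h <- make_fit()
  rrrs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(r) {
    project_margins(h$fit, h$rec, ldl_effect(r, 0))$rrr
  }, 0)
  expect_true(all(diff(rrrs) > 0))
})

test_that("bootstrap CI brackets the point estimate and is reproducible", {
  h <- make_fit()
  a <- project_margins(h$fit, h$rec, n_boot = 50, seed = 9)
  b <- project_margins(h$fit, h$rec, n_boot = 50, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_lt(a$ci[1], a$rrr)
  expect_gt(a$ci[2], a$rrr)
})

test_that("arm interaction test returns a valid p-value under the null", {
  h <- make_fit(n = 2000L, seed = 4)
  p <- test_arm_interaction(h$rec)
  expect_gte(p, 0)
  expect_lte(p, 1)
  expect_gt(p, 0.001) # the generator has no arm-by-LDL interaction
})

test_that("effect-module error paths name the problem", {
  rec <- generate_cohort(cohort_spec(n = 50L, seed = 1))
  rec$event <- 0L
  expect_error(fit_cox(rec), "at least 2 events")
  rec2 <- generate_cohort(cohort_spec(n = 50L, seed = 1))
  expect_error(fit_cox(rec2, covariate_names = "nonexistent"), "'nonexistent'")
  h <- make_fit()
  expect_error(project_margins(h$fit, h$rec, ldl_effect(0.99, 0)), NA)
  expect_error(ldl_effect(1.0), "'mean_reduction'")
  fit_abs <- fit_cox(h$rec, ldl_term = "absolute_change")
  expect_error(project_margins(fit_abs, h$rec), "log attained")
})

test_that("rrr_uncertainty delta method matches the analytic mapping", {
  u <- rrr_uncertainty(0.32, ldl_effect(0.60, 0.05))
  beta <- log(1 - 0.32) / log(1 - 0.60)
  expect_equal(u$log_hr_scale, beta)
  expect_equal(u$sd, beta * 0.4^(beta - 1) * 0.05)
  # finite-difference check of the derivative
  rrr_of <- function(red) 1 - (1 - red)^beta
  fd <- (rrr_of(0.60 + 1e-6) - rrr_of(0.60 - 1e-6)) / 2e-6
  expect_equal(u$sd, fd * 0.05, tolerance = 1e-6)
})
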