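# Two-link evidence synthesis
#
# Link 1: a multivariable Cox proportional-hazards model of recurrent
# ischemic stroke on attained LDL (entered as log LDL, so a fixed
# proportional LDL reduction produces a fixed hazard-ratio shift while the
# absolute benefit shrinks at low baseline LDL).
# Link 2: the summary effect of PCSK9 inhibition on LDL from trial
# meta-analysis - a mean 60% (SD 5 percentage points) proportional reduction.
# The two are combined by predictive margins: each patient's annualized
# recurrence rate is projected under the observed LDL trajectory and under
# the counterfactual 60% reduction of baseline, all other covariates held at
# observed values; the relative risk reduction is one minus the ratio of the
# cohort-averaged rates.

#' PCSK9i effect on LDL
#'
#' @param mean_reduction mean proportional LDL reduction in (0,1); base 0.60.
#' @param sd_reduction standard deviation of the reduction; base 0.05.
#' @return object of class `ldl_effect`.
#' @export
ldl_effect <- function(mean_reduction = 0.60, sd_reduction = 0.05) {
  check_prob(mean_reduction, "mean_reduction", allow_zero = TRUE, allow_one = FALSE)
  check_pos(sd_reduction, "sd_reduction", strict = FALSE)
  structure(list(mean_reduction = mean_reduction, sd_reduction = sd_reduction),
            class = "ldl_effect")
}

#' Fit the multivariable Cox model of recurrent stroke
#'
#' Partial-likelihood fit (Efron tie handling, Newton-Raphson) via
#' [survival::coxph()], with the Breslow baseline cumulative hazard extracted
#' on the uncentered scale.  The LDL exposure enters either as log attained
#' LDL (default; attained = baseline + 30-day change) or as the absolute
#' 30-day change.
#'
#' @param records cohort data.frame (see [generate_cohort()]).
#' @param covariate_names additional adjustment covariates (columns of
#'   `records`).
#' @param ldl_term `"log_attained"` or `"absolute_change"`.
#' @return object of class `cox_fit`: `coefficients`, `covariance`,
#'   `baseline_cumhaz` (step function of days), `n_events`, `concordance`,
#'   plus the fitted `survival::coxph` object.
#' @export
fit_cox <- function(records, covariate_names = c("age_years", "sex"),
                    ldl_term = c("log_attained", "absolute_change")) {
  ldl_term <- match.arg(ldl_term)
  if (sum(records$event) < 2L) stop("need at least 2 events to fit", call. = FALSE)
  missing <- setdiff(covariate_names, names(records))
  if (length(missing)) stop_field(missing[1], "covariate missing from records")
  df <- records
  df$ldl_attained <- df$ldl_baseline + df$ldl_change_30d
  if (any(df$ldl_attained <= 0)) stop("attained LDL must be positive", call. = FALSE)
  ldl_var <- switch(ldl_term,
                    log_attained = "log(ldl_attained)",
                    absolute_change = "ldl_change_30d")
  fml <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~", paste(c(ldl_var, covariate_names), collapse = " + ")))

  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", x = TRUE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("converge|infinite|out of iterations", warns, ignore.case = TRUE)) ||
      any(!is.finite(stats::coef(fit)))) {
    stop(sprintf(
      "Cox fit failed after %d iterations (%s); check for complete separation",
      fit$iter, paste(unique(warns), collapse = "; ")), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(se > 100)) {
    stop("Cox fit unstable (coefficient standard error > 100); likely complete separation",
         call. = FALSE)
  }

  bh <- survival::basehaz(fit, centered = FALSE)
  cumhaz_fun <- stats::approxfun(c(0, bh$time), c(0, bh$hazard),
                                 method = "constant", rule = 2, f = 0)
  out <- list(
    coefficients = stats::coef(fit),
    covariance = stats::vcov(fit),
    baseline_cumhaz = cumhaz_fun,
    baseline_cumhaz_table = bh,
    n_events = sum(records$event),
    concordance = unname(fit$concordance["concordance"]),
    ldl_term = ldl_term,
    covariate_names = covariate_names,
    model = fit
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model of recurrent stroke (%d events, concordance %.3f)\n",
              x$n_events, x$concordance))
  print(round(cbind(coef = x$coefficients,
                    `exp(coef)` = exp(x$coefficients),
                    se = sqrt(diag(x$covariance))), 4))
  invisible(x)
}

# annualized predicted incidence rate per patient:
# Breslow cumulative hazard at 365.25 days times exp(linear predictor),
# with the linear predictor on the same (uncentered) scale as basehaz.
predict_annual_rate <- function(fit, newdata, horizon_days = DAYS_PER_YEAR) {
  nd <- newdata
  nd$ldl_attained <- nd$ldl_baseline + nd$ldl_change_30d
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$model)), data = nd)
  mm <- mm[, names(fit$coefficients), drop = FALSE]
  lp <- drop(mm %*% fit$coefficients)
  fit$baseline_cumhaz(horizon_days) * exp(lp) * DAYS_PER_YEAR / horizon_days
}

#' Project the LDL-lowering effect through the Cox model (predictive margins)
#'
#' For each patient, the annualized recurrence rate is predicted under (a)
#' the observed LDL trajectory and (b) the counterfactual attained LDL of
#' `ldl_baseline * (1 - mean_reduction)`, all other covariates held at
#' observed values.  Both rates are averaged over the cohort and the relative
#' risk reduction is `1 - mean(treated) / mean(control)`.  Because LDL enters
#' the model as log attained LDL, the counterfactual hazard shift is
#' `beta * (log(1 - mean_reduction) + log(ldl_baseline) - log(ldl_attained))`
#' - logarithmically dependent on each patient's baseline LDL.
#'
#' @param fit a [fit_cox()] result using the `log_attained` LDL term.
#' @param records the cohort the margins are averaged over.
#' @param effect an [ldl_effect()].
#' @param n_boot patient-resampling bootstrap replicates for the RRR CI
#'   (0 = no CI).
#' @param conf confidence level for the bootstrap interval.
#' @param seed seed for the bootstrap.
#' @return object of class `effect_estimate`: `rrr`, `rate_control`,
#'   `rate_treated` (events per person-year), `ci`, `n_boot`.
#' @export
project_margins <- function(fit, records, effect = ldl_effect(),
                            horizon_days = DAYS_PER_YEAR,
                            n_boot = 0L, conf = 0.95, seed = 1L) {
  if (fit$ldl_term != "log_attained") {
    stop("predictive margins require the log attained LDL parameterization", call. = FALSE)
  }
  if (effect$mean_reduction >= 1) stop("counterfactual LDL would be non-positive", call. = FALSE)
  check_pos(horizon_days, "horizon_days")
  one_pass <- function(dat) {
    rate_c <- mean(predict_annual_rate(fit, dat, horizon_days))
    cf <- dat
    cf$ldl_change_30d <- -effect$mean_reduction * cf$ldl_baseline
    rate_t <- mean(predict_annual_rate(fit, cf, horizon_days))
    c(rate_c = rate_c, rate_t = rate_t, rrr = 1 - rate_t / rate_c)
  }
  pt <- one_pass(records)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    reps <- replicate(n_boot, {
      one_pass(records[sample.int(nrow(records), replace = TRUE), , drop = FALSE])["rrr"]
    })
    ci <- unname(stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 7))
  }
  structure(list(rrr = unname(pt["rrr"]),
                 rate_control = unname(pt["rate_c"]),
                 rate_treated = unname(pt["rate_t"]),
                 ci = ci, n_boot = as.integer(n_boot),
                 mean_reduction = effect$mean_reduction),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Projected effect of a %.0f%% LDL reduction:\n", 100 * x$mean_reduction))
  cat(sprintf("  annualized recurrence rate %.4f -> %.4f per person-year\n",
              x$rate_control, x$rate_treated))
  cat(sprintf("  relative risk reduction %.1f%%", 100 * x$rrr))
  if (x$n_boot > 0) cat(sprintf(" (%.0f%% CI %.1f%% to %.1f%%, %d bootstrap reps)",
                                95, 100 * x$ci[1], 100 * x$ci[2], x$n_boot))
  cat("\n")
  invisible(x)
}

#' Wald test of the LDL-by-randomization-arm interaction
#'
#' Refits the Cox model with an interaction between the LDL exposure and the
#' randomization arm and returns the two-sided Wald p-value for the
#' interaction coefficient; used to justify pooling the two arms.
#'
#' @inheritParams fit_cox
#' @return p-value in `[0, 1]`.
#' @export
test_arm_interaction <- function(records, covariate_names = c("age_years", "sex"),
                                 ldl_term = c("log_attained", "absolute_change")) {
  ldl_term <- match.arg(ldl_term)
  if (length(unique(records$arm)) < 2L) {
    stop("both randomization arms must be present", call. = FALSE)
  }
  df <- records
  df$ldl_attained <- df$ldl_baseline + df$ldl_change_30d
  ldl_var <- switch(ldl_term,
                    log_attained = "log(ldl_attained)",
                    absolute_change = "ldl_change_30d")
  fml <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~", ldl_var, "* arm +",
    paste(covariate_names, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  idx <- grep(":", names(stats::coef(fit)))
  z <- stats::coef(fit)[idx] / sqrt(diag(stats::vcov(fit)))[idx]
  unname(2 * stats::pnorm(-abs(z)))
}

#' Sampling distribution of the projected relative risk reduction
#'
#' Propagates the uncertainty of the PCSK9i LDL effect: the proportional
#' reduction is drawn from a normal distribution truncated to (0, 1) and the
#' predictive margins are recomputed per draw.
#'
#' @inheritParams project_margins
#' @param n_draws number of Monte Carlo draws.
#' @param seed RNG seed.
#' @return numeric vector of RRR draws, length `n_draws`.
#' @export
rrr_distribution <- function(fit, records, effect = ldl_effect(),
                             n_draws = 1000L, seed = 1L) {
  check_count(n_draws, "n_draws", min = 1L)
  set.seed(seed)
  red <- rtruncnorm(n_draws, effect$mean_reduction, effect$sd_reduction, 0, 1)
  vapply(red, function(r) {
    project_margins(fit, records, ldl_effect(r, 0))$rrr
  }, numeric(1))
}

#' Normal approximation of RRR uncertainty implied by the LDL-reduction SD
#'
#' Delta-method mapping used by the probabilistic sensitivity analysis: given
#' a base-case relative risk reduction and the mean/SD of the proportional
#' LDL reduction, the implied hazard-scale coefficient is
#' `beta = log(1 - rrr) / log(1 - reduction)` and the RRR standard deviation
#' is `|dRRR/dreduction| * sd = beta * (1 - reduction)^(beta - 1) * sd`.
#'
#' @param rrr base-case relative risk reduction (default 0.32).
#' @param effect an [ldl_effect()].
#' @return list with `mean`, `sd`, and the implied `log_hr_scale` beta.
#' @export
rrr_uncertainty <- function(rrr = 0.32, effect = ldl_effect()) {
  check_prob(rrr, "rrr", allow_zero = FALSE, allow_one = FALSE)
  beta <- log(1 - rrr) / log(1 - effect$mean_reduction)
  sd <- beta * (1 - effect$mean_reduction)^(beta - 1) * effect$sd_reduction
  list(mean = rrr, sd = sd, log_hr_scale = beta)
}
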