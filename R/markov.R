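# Three-state Markov cohort model
#
# Health states: stable poststroke, recurrent stroke, death.  Internally the
# stable state is split into on-treatment and off-treatment compartments so
# drug discontinuation can be tracked; the recurrent state is absorbing until
# death (the minimal structure consistent with three mutually exclusive
# health states).  Annual cycles, no half-cycle correction; costs and QALYs
# accrue on end-of-cycle occupancy and are discounted by
# (1 + discount)^-(cycle - 1), i.e. year-1 flows are undiscounted.

MARKOV_STATES <- c("stable_on", "stable_off", "recurrent", "dead")

#' Annual drug price schedule
#'
#' @param name schedule label.
#' @param annual_cost_by_year numeric vector of annual costs (2025 USD), one
#'   per model year.  A single value is recycled to the horizon.
#' @param horizon_years model horizon used for recycling (default 5).
#' @return object of class `price_schedule`.
#' @export
price_schedule <- function(name, annual_cost_by_year, horizon_years = 5L) {
  if (length(annual_cost_by_year) == 1L) {
    annual_cost_by_year <- rep(annual_cost_by_year, horizon_years)
  }
  if (length(annual_cost_by_year) != horizon_years) {
    stop_field("annual_cost_by_year", sprintf("must have length %d", horizon_years))
  }
  if (any(annual_cost_by_year < 0)) stop_field("annual_cost_by_year", "must be non-negative")
  structure(list(name = name, annual_cost_by_year = as.numeric(annual_cost_by_year)),
            class = "price_schedule")
}

#' Built-in drug price schedules
#'
#' Direct-to-consumer (2025 USD) prices: alirocumab $6600/yr, evolocumab
#' $7200/yr, inclisiran $10,800 in year 1 then $7200/yr.  Out-of-pocket
#' (typical Medicare/commercial cost sharing): $600/yr for alirocumab and
#' evolocumab; $2160 in year 1 then $1440/yr for inclisiran.  Federal Supply
#' Schedule entries are placeholder values (synthetic, user-editable; the
#' authoritative FSS list prices are not distributed with the package).
#'
#' @param horizon_years model horizon (default 5).
#' @return named list of lists of [price_schedule()]s:
#'   `dtc`, `oop`, `fss_placeholder`.
#' @export
builtin_schedules <- function(horizon_years = 5L) {
  ps <- function(n, x) price_schedule(n, x, horizon_years)
  list(
    dtc = list(
      alirocumab = ps("alirocumab_dtc", 6600),
      evolocumab = ps("evolocumab_dtc", 7200),
      inclisiran = ps("inclisiran_dtc", c(10800, rep(7200, horizon_years - 1L)))
    ),
    oop = list(
      alirocumab = ps("alirocumab_oop", 600),
      evolocumab = ps("evolocumab_oop", 600),
      inclisiran = ps("inclisiran_oop", c(2160, rep(1440, horizon_years - 1L)))
    ),
    fss_placeholder = list(
      alirocumab = ps("alirocumab_fss_synthetic", 6200),
      evolocumab = ps("evolocumab_fss_synthetic", 5900),
      inclisiran = ps("inclisiran_fss_synthetic", c(9800, rep(6500, horizon_years - 1L)))
    )
  )
}

#' Parameters of the three-state Markov cohort model
#'
#' Base-case values: annual recurrent-stroke probability 14.9\%, background
#' mortality 2\%/yr (stable state), poststroke mortality 5\%/yr (recurrent
#' state), utilities 0.9 (stable) / 0.5 (recurrent) / 0 (dead), 3\% annual
#' discounting of costs and QALYs, 7\%/yr drug discontinuation, treatment
#' relative risk reduction 32\%, 5-year horizon.
#'
#' Stroke-care costs: `c_stroke_event_acute` is a one-time cost on each entry
#' into the recurrent state; `c_stroke_state_annual` accrues on recurrent
#' state occupancy each year.  Defaults were calibrated once (see
#' `analysis/00_calibrate_costs.R`) so the probabilistic median five-year
#' standard-care cost is about $35,900.
#'
#' Two convention switches are exposed (see the methods vignette):
#' \describe{
#'   \item{rrr_scale}{`"rate"` (default) applies the relative risk reduction
#'     on the hazard scale, `p = 1 - (1 - p0)^(1 - rrr)`, keeping
#'     probabilities in [0,1] for any rrr; `"probability"` multiplies the
#'     probability directly.}
#'   \item{drug_cost_basis}{`"alive"` (default) accrues drug cost over all
#'     alive person-time of the intervention arm (arm-level acquisition
#'     budget, not offset by individual discontinuation);
#'     `"on_treatment"` charges only on-treatment occupancy.}
#' }
#' `effect_off_treatment` controls whether the recurrence-risk reduction
#' persists after discontinuation (default `TRUE`: attained lipid control is
#' assumed maintained over the short horizon).
#'
#' @param p_recurrent_annual annual recurrent-stroke probability, stable state.
#' @param p_mort_background_annual annual background mortality, stable state.
#' @param p_mort_poststroke_annual annual mortality, recurrent state.
#' @param u_stable,u_recurrent,u_dead health-state utilities.
#' @param discount_rate_annual annual discount rate for costs and QALYs.
#' @param discontinuation_annual annual probability of drug discontinuation.
#' @param rrr relative risk reduction of recurrent stroke under treatment.
#' @param price a [price_schedule()].
#' @param c_stroke_state_annual annual cost of the recurrent state (USD).
#' @param c_stroke_event_acute one-time cost per recurrent stroke (USD).
#' @param horizon_years number of annual cycles.
#' @param rrr_scale,drug_cost_basis,effect_off_treatment see Details.
#' @return object of class `markov_params`.
#' @export
markov_parameters <- function(p_recurrent_annual = 0.149,
                              p_mort_background_annual = 0.02,
                              p_mort_poststroke_annual = 0.05,
                              u_stable = 0.9,
                              u_recurrent = 0.5,
                              u_dead = 0,
                              discount_rate_annual = 0.03,
                              discontinuation_annual = 0.07,
                              rrr = 0.32,
                              price = builtin_schedules()$dtc$alirocumab,
                              c_stroke_state_annual = 16950,
                              c_stroke_event_acute = 20000,
                              horizon_years = 5L,
                              rrr_scale = c("rate", "probability"),
                              drug_cost_basis = c("alive", "on_treatment"),
                              effect_off_treatment = TRUE) {
  p <- list(
    p_recurrent_annual = check_prob(p_recurrent_annual, "p_recurrent_annual"),
    p_mort_background_annual = check_prob(p_mort_background_annual, "p_mort_background_annual"),
    p_mort_poststroke_annual = check_prob(p_mort_poststroke_annual, "p_mort_poststroke_annual"),
    u_stable = check_prob(u_stable, "u_stable"),
    u_recurrent = check_prob(u_recurrent, "u_recurrent"),
    u_dead = u_dead,
    discount_rate_annual = check_pos(discount_rate_annual, "discount_rate_annual", strict = FALSE),
    discontinuation_annual = check_prob(discontinuation_annual, "discontinuation_annual"),
    rrr = rrr,
    price = price,
    c_stroke_state_annual = check_pos(c_stroke_state_annual, "c_stroke_state_annual", strict = FALSE),
    c_stroke_event_acute = check_pos(c_stroke_event_acute, "c_stroke_event_acute", strict = FALSE),
    horizon_years = check_count(horizon_years, "horizon_years", min = 1L),
    rrr_scale = match.arg(rrr_scale),
    drug_cost_basis = match.arg(drug_cost_basis),
    effect_off_treatment = isTRUE(effect_off_treatment)
  )
  if (u_dead != 0) stop_field("u_dead", "must be 0")
  if (!is.numeric(rrr) || rrr >= 1) stop_field("rrr", "must be a number < 1")
  if (!inherits(price, "price_schedule")) stop_field("price", "must be a price_schedule")
  if (length(price$annual_cost_by_year) != p$horizon_years) {
    stop_field("price", "schedule length must equal horizon_years")
  }
  validate_exit_probs(p)
  class(p) <- "markov_params"
  p
}

validate_exit_probs <- function(p) {
  p_treat <- treated_recurrence_prob(p$p_recurrent_annual, p$rrr, p$rrr_scale)
  exits <- c(p$p_recurrent_annual + p$p_mort_background_annual,
             p_treat + p$p_mort_background_annual,
             p$p_mort_poststroke_annual)
  if (any(exits > 1)) {
    stop_field("p_recurrent_annual", "combined one-cycle exit probability exceeds 1")
  }
  invisible(p)
}

treated_recurrence_prob <- function(p, rrr, scale = c("rate", "probability")) {
  scale <- match.arg(scale)
  switch(scale,
         rate = 1 - (1 - p)^(1 - rrr),
         probability = pmax(0, p * (1 - rrr)))
}

#' Transition matrix of the three-state model
#'
#' Row-stochastic matrix over `{stable_on, stable_off, recurrent, dead}`.
#' From the stable compartments patients move to the recurrent state
#' (treatment-modified for on-treatment occupancy when `arm = "pcsk9i"`, and
#' for off-treatment occupancy as well when `effect_off_treatment` is TRUE),
#' to death with background mortality, or discontinue (stable_on to
#' stable_off); the recurrent state exits only to death (poststroke
#' mortality); death is absorbing.
#'
#' @param params a [markov_parameters()] object.
#' @param arm `"standard"` or `"pcsk9i"`.
#' @return 4 x 4 matrix with rows summing to 1 exactly.
#' @export
build_transition_matrix <- function(params, arm = c("standard", "pcsk9i")) {
  arm <- match.arg(arm)
  p <- params
  treated <- arm == "pcsk9i"
  p_rec_on <- if (treated) {
    treated_recurrence_prob(p$p_recurrent_annual, p$rrr, p$rrr_scale)
  } else p$p_recurrent_annual
  p_rec_off <- if (treated && p$effect_off_treatment) p_rec_on else p$p_recurrent_annual
  d <- p$discontinuation_annual
  m <- matrix(0, 4, 4, dimnames = list(MARKOV_STATES, MARKOV_STATES))
  stay_on <- 1 - p_rec_on - p$p_mort_background_annual
  m["stable_on", ] <- c(stay_on * (1 - d), stay_on * d, p_rec_on, p$p_mort_background_annual)
  stay_off <- 1 - p_rec_off - p$p_mort_background_annual
  m["stable_off", ] <- c(0, stay_off, p_rec_off, p$p_mort_background_annual)
  m["recurrent", ] <- c(0, 0, 1 - p$p_mort_poststroke_annual, p$p_mort_poststroke_annual)
  m["dead", ] <- c(0, 0, 0, 1)
  m
}

#' Run the Markov cohort model for one arm
#'
#' The cohort starts fully in the stable poststroke state (on treatment for
#' the intervention arm) and is propagated through `horizon_years` annual
#' cycles.  Per cycle, QALYs accrue as utility-weighted end-of-cycle
#' occupancy; care costs as the annual recurrent-state cost on recurrent
#' occupancy plus the acute event cost on new entries into the recurrent
#' state; drug costs on the year's scheduled price times alive (or
#' on-treatment) occupancy of the intervention arm.  All flows are discounted
#' by `(1 + discount)^-(cycle - 1)`.
#'
#' @param params a [markov_parameters()] object.
#' @param arm `"standard"` or `"pcsk9i"`.
#' @return object of class `arm_result`: `total_cost_discounted`,
#'   `total_qaly_discounted`, `drug_cost_component`, `care_cost_component`,
#'   `occupancy_trace` ((horizon+1) x 4 matrix, rows summing to 1),
#'   `new_recurrent` (per-cycle inflow into the recurrent state).
#' @export
run_cohort_model <- function(params, arm = c("standard", "pcsk9i")) {
  arm <- match.arg(arm)
  p <- params
  m <- build_transition_matrix(p, arm)
  occ <- if (arm == "pcsk9i") c(1, 0, 0, 0) else c(0, 1, 0, 0)
  trace <- matrix(NA_real_, p$horizon_years + 1L, 4,
                  dimnames = list(0:p$horizon_years, MARKOV_STATES))
  trace[1L, ] <- occ
  qaly <- drug <- care <- 0
  new_rec <- numeric(p$horizon_years)
  u <- c(p$u_stable, p$u_stable, p$u_recurrent, p$u_dead)
  for (k in seq_len(p$horizon_years)) {
    inflow <- occ[1] * m[1, 3] + occ[2] * m[2, 3]
    occ <- as.numeric(occ %*% m)
    trace[k + 1L, ] <- occ
    df <- (1 + p$discount_rate_annual)^(-(k - 1))
    qaly <- qaly + df * sum(u * occ)
    care <- care + df * (p$c_stroke_state_annual * occ[3] +
                           p$c_stroke_event_acute * inflow)
    if (arm == "pcsk9i") {
      payers <- if (p$drug_cost_basis == "alive") sum(occ[1:3]) else occ[1]
      drug <- drug + df * p$price$annual_cost_by_year[k] * payers
    }
    new_rec[k] <- inflow
  }
  structure(list(total_cost_discounted = drug + care,
                 total_qaly_discounted = qaly,
                 drug_cost_component = drug,
                 care_cost_component = care,
                 occupancy_trace = trace,
                 new_recurrent = new_rec,
                 arm = arm),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm: discounted cost $%.0f (drug %.0f + care %.0f), QALYs %.3f\n",
              x$arm, x$total_cost_discounted, x$drug_cost_component,
              x$care_cost_component, x$total_qaly_discounted))
  invisible(x)
}

#' Incremental cost-effectiveness of the intervention arm
#'
#' Runs both arms under one parameterization and returns incremental cost,
#' incremental QALYs and the ICER.  The ICER is `NA` with an explanatory flag
#' when incremental QALYs are zero (`"undefined"`), when the intervention
#' dominates (`"dominant"`: cheaper and more effective) or is dominated
#' (`"dominated"`: costlier and less effective).
#'
#' @param params a [markov_parameters()] object.
#' @return list with `delta_cost`, `delta_qaly`, `icer`, `flag`, and the two
#'   `arm_result`s.
#' @export
incremental <- function(params) {
  std <- run_cohort_model(params, "standard")
  trt <- run_cohort_model(params, "pcsk9i")
  dc <- trt$total_cost_discounted - std$total_cost_discounted
  dq <- trt$total_qaly_discounted - std$total_qaly_discounted
  if (dq == 0) {
    flag <- "undefined"; icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    flag <- "dominant"; icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    flag <- "dominated"; icer <- NA_real_
  } else {
    flag <- "ok"; icer <- dc / dq
  }
  list(delta_cost = dc, delta_qaly = dq, icer = icer, flag = flag,
       standard = std, pcsk9i = trt)
}

#' Read / write Markov parameters as YAML
#'
#' @param params a [markov_parameters()] object.
#' @param path file path.
#' @export
write_markov_parameters <- function(params, path) {
  x <- unclass(params)
  x$price <- unclass(x$price)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_markov_parameters
#' @export
read_markov_parameters <- function(path) {
  x <- yaml::read_yaml(path)
  x$price <- price_schedule(x$price$name, x$price$annual_cost_by_year, x$horizon_years)
  do.call(markov_parameters, x)
}
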