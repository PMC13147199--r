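# Pricing and sensitivity scenarios
#
# A scenario is a declarative modification of the base case: an alternative
# drug price schedule, an override of the relative risk reduction (shifting
# the mean of its PSA distribution while keeping its spread), or a multiplier
# on both stroke-care costs.  Threshold prices are found by bisection on a
# flat annual price, reusing one common set of Monte Carlo parameter draws
# across all candidate prices so the cost-effectiveness probability is exactly
# monotone in price.

#' Declare a scenario
#'
#' @param name scenario label.
#' @param price optional [price_schedule()] replacing the base schedule.
#' @param rrr_override optional relative risk reduction; shifts the mean of
#'   the PSA distribution of the rrr to this value while keeping its standard
#'   deviation (a point mass stays a point mass at the new value).
#' @param stroke_cost_multiplier optional positive multiplier applied to both
#'   the annual recurrent-state cost and the acute per-event cost (means of
#'   their PSA distributions scale with them; coefficients of variation are
#'   kept).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, price = NULL, rrr_override = NULL,
                          stroke_cost_multiplier = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_field("name", "must be a non-empty string")
  }
  if (!is.null(price) && !inherits(price, "price_schedule")) {
    stop_field("price", "must be a price_schedule")
  }
  if (!is.null(rrr_override)) {
    check_prob(rrr_override, "rrr_override", allow_zero = FALSE, allow_one = FALSE)
  }
  if (!is.null(stroke_cost_multiplier)) {
    check_pos(stroke_cost_multiplier, "stroke_cost_multiplier")
  }
  structure(list(name = name, price = price, rrr_override = rrr_override,
                 stroke_cost_multiplier = stroke_cost_multiplier),
            class = "scenario_spec")
}

# apply a scenario to (base, dists); returns the modified pair
apply_scenario <- function(base, dists, scenario) {
  if (!inherits(scenario, "scenario_spec")) stop_field("scenario", "must be a scenario_spec")
  b <- base
  d <- dists
  if (!is.null(scenario$price)) {
    if (length(scenario$price$annual_cost_by_year) != b$horizon_years) {
      stop_field("price", "schedule length must equal horizon_years")
    }
    b$price <- scenario$price
  }
  if (!is.null(scenario$rrr_override)) {
    b$rrr <- scenario$rrr_override
    old_sd <- if (d$rrr$kind == "normal_trunc01") d$rrr$sd else 0
    d$rrr <- dist_normal_trunc01(scenario$rrr_override, old_sd)
    validate_exit_probs(b)
  }
  if (!is.null(scenario$stroke_cost_multiplier)) {
    m <- scenario$stroke_cost_multiplier
    b$c_stroke_state_annual <- m * b$c_stroke_state_annual
    b$c_stroke_event_acute <- m * b$c_stroke_event_acute
    d$c_stroke_state_annual <- rescale_gamma_mean(d$c_stroke_state_annual, m)
    d$c_stroke_event_acute <- rescale_gamma_mean(d$c_stroke_event_acute, m)
  }
  list(base = b, dists = d)
}

rescale_gamma_mean <- function(d, m) {
  if (d$kind == "point") return(dist_point(m * d$mean))
  dist_gamma(m * d$mean, d$cv)
}

#' Run the PSA under a scenario
#'
#' Applies the scenario's modifications to the base parameters and the PSA
#' distributions, then calls [run_psa()].  An empty scenario reproduces the
#' base-case PSA bit for bit at equal seed.
#'
#' @param base a [markov_parameters()] object.
#' @param dists a [parameter_distributions()] object.
#' @param scenario a [scenario_spec()].
#' @inheritParams run_psa
#' @return a `psa_result` with the scenario attached as `$scenario`.
#' @export
run_scenario <- function(base, dists, scenario, n_iter = 1000L, seed = 1L,
                         wtps = c(50000, 120000)) {
  mod <- apply_scenario(base, dists, scenario)
  out <- run_psa(mod$base, mod$dists, n_iter = n_iter, seed = seed, wtps = wtps)
  out$scenario <- scenario
  out
}

#' Threshold flat annual price for a target cost-effectiveness probability
#'
#' Finds the flat annual drug price at which the probability of
#' cost-effectiveness at willingness-to-pay `wtp` equals `target`, by
#' bisection.  One set of `n_iter` parameter draws (common random numbers) is
#' shared across all candidate prices; since per-iteration net monetary
#' benefit is strictly decreasing in price, the estimated probability is
#' monotone non-increasing in price and bisection is valid.  The search stops
#' when the bracketing interval is at most `tol` dollars wide (default $50)
#' and returns its midpoint.
#'
#' @param base a [markov_parameters()] object; its price schedule is replaced
#'   by the flat candidate price.
#' @param dists a [parameter_distributions()] object.  The
#'   `price_multiplier` uncertainty still applies to the candidate price.
#' @param wtp willingness-to-pay threshold (USD/QALY).
#' @param target target cost-effectiveness probability in (0, 1).
#' @param n_iter Monte Carlo iterations.
#' @param seed RNG seed for the shared draws.
#' @param price_bounds search interval `c(lo, hi)`; an error is raised when
#'   the probability at `lo` is below the target or the probability at `hi`
#'   is above it (target not bracketed).
#' @param tol bracket width at which the search stops (USD).
#' @return object of class `threshold_result`: `price`, `probability` (at the
#'   returned price), `bracket`, `wtp`, `target`, and `search_trace` (one row
#'   per evaluated price).
#' @export
threshold_price <- function(base, dists, wtp = 120000, target = 0.5,
                            n_iter = 1000L, seed = 1L,
                            price_bounds = c(0, 40000), tol = 50) {
  check_prob(target, "target", allow_zero = FALSE, allow_one = FALSE)
  check_pos(wtp, "wtp")
  check_count(n_iter, "n_iter", min = 1L)
  check_pos(tol, "tol")
  if (length(price_bounds) != 2L || any(price_bounds < 0) || diff(price_bounds) <= 0) {
    stop_field("price_bounds", "must be an increasing pair of non-negative prices")
  }

  set.seed(seed)
  draws <- draw_parameter_matrix(base, dists, n_iter)

  # Per iteration, QALYs and care costs do not depend on the drug price and
  # the drug cost is linear in it: running the intervention arm at a flat
  # unit price yields the discounted payer-time coefficient directly.
  dq <- dcare <- coef_price <- numeric(n_iter)
  unit <- price_schedule("unit_flat", 1, base$horizon_years)
  for (i in seq_len(n_iter)) {
    p <- apply_draw(base, draws[i, ])
    p$price <- unit
    std <- run_cohort_model(p, "standard")
    trt <- run_cohort_model(p, "pcsk9i")
    dq[i] <- trt$total_qaly_discounted - std$total_qaly_discounted
    dcare[i] <- trt$care_cost_component - std$total_cost_discounted
    coef_price[i] <- trt$drug_cost_component * draws[i, "price_multiplier"]
  }
  prob_at <- function(price) mean(wtp * dq - (dcare + coef_price * price) > 0)

  lo <- price_bounds[1]; hi <- price_bounds[2]
  p_lo <- prob_at(lo); p_hi <- prob_at(hi)
  trace <- data.frame(price = c(lo, hi), probability = c(p_lo, p_hi))
  if (p_lo < target || p_hi > target) {
    stop(sprintf(
      "price_bounds [%g, %g] do not bracket the %.0f%% target (probabilities %.3f and %.3f)",
      lo, hi, 100 * target, p_lo, p_hi), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p_mid <- prob_at(mid)
    trace <- rbind(trace, data.frame(price = mid, probability = p_mid))
    if (p_mid >= target) lo <- mid else hi <- mid
  }
  price <- (lo + hi) / 2
  structure(list(price = price, probability = prob_at(price),
                 bracket = c(lo = lo, hi = hi), wtp = wtp, target = target,
                 n_iter = n_iter, seed = seed, search_trace = trace),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Threshold price for %.0f%% cost-effectiveness at $%s/QALY: $%.0f/yr (bracket %.0f-%.0f, %d evaluations)\n",
    100 * x$target, format(x$wtp, big.mark = ","), x$price,
    x$bracket["lo"], x$bracket["hi"], nrow(x$search_trace)))
  invisible(x)
}
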