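# Probabilistic sensitivity analysis
#
# Parameter uncertainty is propagated with method-of-moments beta
# distributions for probabilities and utilities, gamma distributions for
# costs (specified by coefficient of variation), and a truncated normal for
# the treatment relative risk reduction.  Each Monte Carlo iteration draws
# one parameter set, runs both arms of the Markov model on it (common random
# numbers across arms), and records incremental cost, incremental QALYs and
# net monetary benefit at each willingness-to-pay threshold.

#' Method-of-moments beta parameters
#'
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean (1 - mean) / sd^2 - 1`; the resulting beta distribution has
#' exactly the requested mean and standard deviation.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return named vector `c(alpha, beta)`.
#' @export
moments_to_beta <- function(mean, sd) {
  check_prob(mean, "mean", allow_zero = FALSE, allow_one = FALSE)
  check_pos(sd, "sd")
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) {
    stop_field("sd", sprintf("too large for a beta distribution with mean %g (needs sd^2 < %g)",
                             mean, mean * (1 - mean)))
  }
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' `shape = 1 / cv^2`, `scale = mean * cv^2`.
#'
#' @param mean mean, positive.
#' @param cv coefficient of variation, positive.
#' @return named vector `c(shape, scale)`.
#' @export
moments_to_gamma <- function(mean, cv) {
  check_pos(mean, "mean")
  check_pos(cv, "cv")
  c(shape = 1 / cv^2, scale = mean * cv^2)
}

# distribution spec constructors; sd/cv of 0 (or below tolerance) collapse to
# a point mass so degenerate limits stay exact
POINT_MASS_TOL <- 1e-6

dist_beta <- function(mean, sd) {
  if (sd < POINT_MASS_TOL) return(dist_point(mean))
  ab <- moments_to_beta(mean, sd)
  structure(list(kind = "beta", mean = mean, sd = sd,
                 alpha = ab["alpha"], beta = ab["beta"]), class = "psa_dist")
}

dist_gamma <- function(mean, cv) {
  if (cv < POINT_MASS_TOL) return(dist_point(mean))
  sh <- moments_to_gamma(mean, cv)
  structure(list(kind = "gamma", mean = mean, cv = cv,
                 shape = sh["shape"], scale = sh["scale"]), class = "psa_dist")
}

dist_normal_trunc01 <- function(mean, sd) {
  if (sd < POINT_MASS_TOL) return(dist_point(mean))
  structure(list(kind = "normal_trunc01", mean = mean, sd = sd), class = "psa_dist")
}

dist_point <- function(value) {
  structure(list(kind = "point", mean = value), class = "psa_dist")
}

draw_dist <- function(d, n) {
  switch(d$kind,
         point = rep(d$mean, n),
         beta = stats::rbeta(n, d$alpha, d$beta),
         gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
         normal_trunc01 = rtruncnorm(n, d$mean, d$sd, 0, 1),
         stop("unknown distribution kind: ", d$kind))
}

#' Parameter distributions for the probabilistic sensitivity analysis
#'
#' Defaults follow the base case: recurrence probability beta(mean 0.149,
#' sd 0.008); background and poststroke mortality beta with sd equal to 20\%
#' of the mean; utilities beta(0.9, sd 0.15) and beta(0.5, sd 0.15);
#' drug price and both stroke-care costs gamma with a 20\% coefficient of
#' variation; relative risk reduction normal truncated to (0, 1) with the sd
#' implied by the LDL-reduction SD through the evidence-synthesis mapping
#' (see [rrr_uncertainty()]).  Any sd/cv of 0 yields a point mass.  The drug
#' price uncertainty is drawn as a single multiplier applied to the whole
#' annual schedule.
#'
#' @param base a [markov_parameters()] object supplying the means.
#' @param sd_recurrent sd of the recurrence probability.
#' @param cv_mortality relative sd of the two mortality probabilities.
#' @param sd_utility sd of both health-state utilities.
#' @param cv_cost coefficient of variation for drug price and care costs.
#' @param rrr_sd sd of the relative risk reduction (default from
#'   [rrr_uncertainty()] at the base-case rrr).
#' @return named list of distribution specs, class `psa_dists`.
#' @export
parameter_distributions <- function(base = markov_parameters(),
                                    sd_recurrent = 0.008,
                                    cv_mortality = 0.20,
                                    sd_utility = 0.15,
                                    cv_cost = 0.20,
                                    rrr_sd = NULL) {
  rrr_sd <- rrr_sd %||% rrr_uncertainty(base$rrr)$sd
  structure(list(
    p_recurrent_annual = dist_beta(base$p_recurrent_annual, sd_recurrent),
    p_mort_background_annual = dist_beta(base$p_mort_background_annual,
                                         cv_mortality * base$p_mort_background_annual),
    p_mort_poststroke_annual = dist_beta(base$p_mort_poststroke_annual,
                                         cv_mortality * base$p_mort_poststroke_annual),
    u_stable = dist_beta(base$u_stable, sd_utility),
    u_recurrent = dist_beta(base$u_recurrent, sd_utility),
    rrr = dist_normal_trunc01(base$rrr, rrr_sd),
    price_multiplier = dist_gamma(1, cv_cost),
    c_stroke_state_annual = dist_gamma(max(base$c_stroke_state_annual, POINT_MASS_TOL), cv_cost),
    c_stroke_event_acute = dist_gamma(max(base$c_stroke_event_acute, POINT_MASS_TOL), cv_cost)
  ), class = "psa_dists")
}

# draw a matrix of parameter values, redrawing rows that violate the Markov
# invariants (combined exit probability > 1)
draw_parameter_matrix <- function(base, dists, n_iter) {
  draws <- vapply(dists, draw_dist, numeric(n_iter), n = n_iter)
  if (n_iter == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(dists)))
  redraws <- 0L
  repeat {
    p_treat <- treated_recurrence_prob(draws[, "p_recurrent_annual"], draws[, "rrr"],
                                       base$rrr_scale)
    bad <- (draws[, "p_recurrent_annual"] + draws[, "p_mort_background_annual"] > 1) |
      (p_treat + draws[, "p_mort_background_annual"] > 1)
    if (!any(bad)) break
    redraws <- redraws + sum(bad)
    draws[bad, ] <- vapply(dists, draw_dist, numeric(sum(bad)), n = sum(bad))
  }
  if (redraws > 0.1 * n_iter) {
    warning(sprintf("PSA redraw rate above 10%% (%d redraws for %d iterations)",
                    redraws, n_iter))
  }
  attr(draws, "redraws") <- redraws
  draws
}

# fast path: modify a validated markov_params without re-validating
apply_draw <- function(base, row) {
  p <- base
  p$p_recurrent_annual <- row[["p_recurrent_annual"]]
  p$p_mort_background_annual <- row[["p_mort_background_annual"]]
  p$p_mort_poststroke_annual <- row[["p_mort_poststroke_annual"]]
  p$u_stable <- row[["u_stable"]]
  p$u_recurrent <- row[["u_recurrent"]]
  p$rrr <- row[["rrr"]]
  p$c_stroke_state_annual <- row[["c_stroke_state_annual"]]
  p$c_stroke_event_acute <- row[["c_stroke_event_acute"]]
  p$price$annual_cost_by_year <- base$price$annual_cost_by_year * row[["price_multiplier"]]
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Per iteration, one parameter set is drawn from `dists` and both arms are
#' run on it (common random numbers).  Cost-effectiveness at willingness to
#' pay `lambda` is decided by positive incremental net monetary benefit,
#' `lambda * dQALY - dCost > 0` (ties count as not cost-effective), which
#' handles dominance and negative incremental QALYs unambiguously.
#' Monte Carlo uncertainty of each cost-effectiveness probability is
#' summarized with a 95\% Wilson score interval.
#'
#' @param base a [markov_parameters()] object (the distribution means).
#' @param dists a [parameter_distributions()] object.
#' @param n_iter number of Monte Carlo iterations (base case 1000).
#' @param seed RNG seed; results are a pure function of inputs and seed.
#' @param wtps willingness-to-pay thresholds (USD/QALY).
#' @return object of class `psa_result`: `draws` (one row per iteration with
#'   parameter values, per-arm costs/QALYs, incrementals, ICER and NMB per
#'   threshold), `summaries`, `ce_probability`, `n_iter`, `seed`, `wtps`.
#' @export
run_psa <- function(base = markov_parameters(), dists = parameter_distributions(base),
                    n_iter = 1000L, seed = 1L, wtps = c(50000, 120000)) {
  check_count(n_iter, "n_iter", min = 1L)
  if (!length(wtps)) stop_field("wtps", "must be non-empty")
  set.seed(seed)
  draws <- draw_parameter_matrix(base, dists, n_iter)

  res <- matrix(NA_real_, n_iter, 6,
                dimnames = list(NULL, c("cost_standard", "cost_pcsk9i",
                                        "qaly_standard", "qaly_pcsk9i",
                                        "delta_cost", "delta_qaly")))
  for (i in seq_len(n_iter)) {
    p <- apply_draw(base, draws[i, ])
    std <- run_cohort_model(p, "standard")
    trt <- run_cohort_model(p, "pcsk9i")
    res[i, ] <- c(std$total_cost_discounted, trt$total_cost_discounted,
                  std$total_qaly_discounted, trt$total_qaly_discounted,
                  trt$total_cost_discounted - std$total_cost_discounted,
                  trt$total_qaly_discounted - std$total_qaly_discounted)
  }
  icer <- ifelse(res[, "delta_qaly"] == 0, NA_real_,
                 res[, "delta_cost"] / res[, "delta_qaly"])
  out <- data.frame(iteration = seq_len(n_iter), draws, res, icer = icer,
                    check.names = FALSE)
  for (w in wtps) {
    out[[sprintf("nmb_%d", as.integer(w))]] <- w * res[, "delta_qaly"] - res[, "delta_cost"]
  }

  ce <- lapply(wtps, function(w) {
    k <- sum(out[[sprintf("nmb_%d", as.integer(w))]] > 0)
    wi <- wilson_interval(k, n_iter)
    c(point = k / n_iter, lo = unname(wi[1]), hi = unname(wi[2]))
  })
  names(ce) <- as.character(wtps)

  summaries <- list(
    cost_standard = summary_block(out$cost_standard),
    cost_pcsk9i = summary_block(out$cost_pcsk9i),
    qaly_standard = summary_block(out$qaly_standard),
    qaly_pcsk9i = summary_block(out$qaly_pcsk9i),
    delta_cost = summary_block(out$delta_cost),
    delta_qaly = summary_block(out$delta_qaly),
    icer = summary_block(out$icer)
  )
  structure(list(draws = out, n_iter = n_iter, seed = seed, wtps = wtps,
                 ce_probability = ce, summaries = summaries,
                 redraws = attr(draws, "redraws"), base = base, dists = dists),
            class = "psa_result")
}

summary_block <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                       type = 7, na.rm = TRUE)
  c(mean = mean(x, na.rm = TRUE), p2.5 = q[1], q1 = q[2], median = q[3],
    q3 = q[4], p97.5 = q[5])
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d), drug schedule '%s'\n",
              x$n_iter, x$seed, x$base$price$name))
  s <- x$summaries
  cat(sprintf("  incremental cost  median $%.0f (95%% CI %.0f to %.0f)\n",
              s$delta_cost["median"], s$delta_cost["p2.5"], s$delta_cost["p97.5"]))
  cat(sprintf("  incremental QALYs median %.3f (IQR %.3f to %.3f), mean %.3f\n",
              s$delta_qaly["median"], s$delta_qaly["q1"], s$delta_qaly["q3"],
              s$delta_qaly["mean"]))
  for (w in names(x$ce_probability)) {
    ce <- x$ce_probability[[w]]
    cat(sprintf("  P(cost-effective) at $%s/QALY: %.1f%% (%.1f-%.1f)\n",
                w, 100 * ce["point"], 100 * ce["lo"], 100 * ce["hi"]))
  }
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' Used for the Monte Carlo sampling uncertainty of cost-effectiveness
#' probabilities estimated from a finite number of PSA iterations.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param confidence confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`, both in `[0, 1]`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  check_count(n, "n", min = 1L)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n || k != as.integer(k)) {
    stop_field("k", "must be an integer in [0, n]")
  }
  check_prob(confidence, "confidence", allow_zero = FALSE, allow_one = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Export the cost-effectiveness plane
#'
#' One row per PSA iteration with incremental QALYs, incremental cost, the
#' ICER, and a cost-effectiveness flag per willingness-to-pay threshold
#' (positive net monetary benefit, the same rule as [run_psa()]).
#'
#' @param result a [run_psa()] result.
#' @return data.frame with `n_iter` rows.
#' @export
plane_export <- function(result) {
  d <- result$draws
  out <- data.frame(iteration = d$iteration,
                    delta_qaly = d$delta_qaly,
                    delta_cost = d$delta_cost,
                    icer = d$icer)
  for (w in result$wtps) {
    out[[sprintf("ce_at_%d", as.integer(w))]] <-
      as.integer(d[[sprintf("nmb_%d", as.integer(w))]] > 0)
  }
  out
}
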