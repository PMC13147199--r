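# Reporting and end-to-end pipeline
#
# make_table2() renders the main cost-effectiveness table (one row per drug:
# probabilistic medians with 95% credible intervals for per-arm costs and
# QALYs, incrementals, ICER, and cost-effectiveness probabilities).
# run_cea_pipeline() drives the whole analysis from a YAML configuration:
# synthetic cohort -> Cox fit -> predictive margins -> Markov PSA per drug ->
# scenario and threshold analyses -> files on disk with a provenance sidecar.

fmt_ci <- function(s, digits = 0, scale = 1) {
  f <- function(v) formatC(scale * v, format = "f", digits = digits, big.mark = ",")
  sprintf("%s (%s to %s)", f(s[["median"]]), f(s[["p2.5"]]), f(s[["p97.5"]]))
}

#' Main cost-effectiveness results table
#'
#' One row per PSA result (typically one per drug): probabilistic median and
#' 95\% credible interval of per-arm discounted costs and QALYs, incremental
#' cost and QALYs, the median ICER, and the probability of cost-effectiveness
#' at each willingness-to-pay threshold of the results.
#'
#' @param results named list of [run_psa()] results; names label the rows.
#' @return data.frame of formatted strings plus numeric `icer_median` and one
#'   numeric `p_ce_<wtp>` column per threshold.
#' @export
make_table2 <- function(results) {
  if (!length(results)) stop_field("results", "must be a non-empty list of psa_result objects")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop_field("results", "must be a named list")
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (!inherits(r, "psa_result")) stop_field(nm, "is not a psa_result")
    s <- r$summaries
    row <- data.frame(
      comparison = nm,
      cost_standard = fmt_ci(s$cost_standard),
      cost_pcsk9i = fmt_ci(s$cost_pcsk9i),
      qaly_standard = fmt_ci(s$qaly_standard, digits = 2),
      qaly_pcsk9i = fmt_ci(s$qaly_pcsk9i, digits = 2),
      incremental_cost = fmt_ci(s$delta_cost),
      incremental_qaly = fmt_ci(s$delta_qaly, digits = 2),
      icer_median = unname(s$icer["median"]),
      stringsAsFactors = FALSE
    )
    for (w in names(r$ce_probability)) {
      ce <- r$ce_probability[[w]]
      row[[sprintf("p_ce_%s", w)]] <- unname(ce["point"])
      row[[sprintf("ce_%s", w)]] <- sprintf("%.1f (%.1f-%.1f)", 100 * ce["point"],
                                            100 * ce["lo"], 100 * ce["hi"])
    }
    row
  })
  do.call(rbind, rows)
}

PIPELINE_REQUIRED <- c("seed", "n_iter", "drugs", "schedule_set", "wtps")

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_field("config", "must be a list (or a path to a YAML file)")
  missing <- setdiff(PIPELINE_REQUIRED, names(config))
  if (length(missing)) stop_field(missing[1], "required pipeline configuration field is missing")
  check_count(config$seed, "seed", min = -.Machine$integer.max)
  check_count(config$n_iter, "n_iter", min = 1L)
  sets <- names(builtin_schedules())
  if (!config$schedule_set %in% sets) {
    stop_field("schedule_set", paste("must be one of", paste(sets, collapse = ", ")))
  }
  drugs <- names(builtin_schedules()[[config$schedule_set]])
  bad <- setdiff(config$drugs, drugs)
  if (length(bad)) stop_field("drugs", paste("unknown drug:", bad[1]))
  if (!is.numeric(config$wtps) || !length(config$wtps) || any(config$wtps <= 0)) {
    stop_field("wtps", "must be positive willingness-to-pay values")
  }
  invisible(config)
}

#' Run the full cost-effectiveness pipeline
#'
#' Stages: (1) generate the synthetic cohort; (2) fit the Cox model and
#' project the relative risk reduction of the configured LDL effect by
#' predictive margins; (3) run the probabilistic Markov analysis once per
#' configured drug; (4) run any configured scenarios and threshold-price
#' searches.  Everything is a pure function of the configuration, so repeated
#' runs write byte-identical results.
#'
#' Configuration fields: `seed`, `n_iter`, `drugs`, `schedule_set`, `wtps`
#' (required); `cohort` (arguments of [cohort_spec()]), `effect` (arguments
#' of [ldl_effect()]), `model` (argument overrides of [markov_parameters()]),
#' `use_estimated_rrr` (default `TRUE`: plug the margins estimate into the
#' model; `FALSE` keeps `model$rrr`), `scenarios` (list of
#' [scenario_spec()] argument lists, each applied to the first drug),
#' `thresholds` (list of lists with `wtp`, `target`), `output_dir`.
#'
#' @param config a list, or the path of a YAML file containing one.
#' @param output_dir where files are written (default from the config, or no
#'   files when absent there too).  Writes `table2.csv`,
#'   `ce_probabilities.csv`, `cohort_summary.txt`, `thresholds.csv` (when
#'   requested) and a `provenance.yaml` sidecar.
#' @return list of class `cea_pipeline`: `config`, `cohort_summary`,
#'   `effect_estimate`, `psa` (named by drug), `scenarios`, `thresholds`,
#'   `table2`, `files`.
#' @export
run_cea_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_field("config", paste("file not found:", config))
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  output_dir <- output_dir %||% config$output_dir

  # stage 1: cohort
  spec <- do.call(cohort_spec, config$cohort %||% list())
  records <- generate_cohort(spec)
  cohort_summary <- summarize_cohort(records)

  # stage 2: evidence synthesis
  effect <- do.call(ldl_effect, config$effect %||% list())
  fit <- fit_cox(records)
  est <- project_margins(fit, records, effect)

  # stage 3: decision model per drug
  model_args <- config$model %||% list()
  if (!is.null(model_args$price)) stop_field("model$price", "set drug prices via 'drugs'/'schedule_set'")
  if (isTRUE(config$use_estimated_rrr %||% TRUE)) model_args$rrr <- est$rrr
  schedules <- builtin_schedules(model_args$horizon_years %||% 5L)[[config$schedule_set]]
  rrr_sd <- rrr_uncertainty(model_args$rrr %||% 0.32, effect)$sd
  psa <- lapply(stats::setNames(config$drugs, config$drugs), function(drug) {
    base <- do.call(markov_parameters, c(model_args, list(price = schedules[[drug]])))
    dists <- parameter_distributions(base, rrr_sd = rrr_sd)
    run_psa(base, dists, n_iter = config$n_iter, seed = config$seed, wtps = config$wtps)
  })
  base1 <- psa[[1L]]$base
  dists1 <- psa[[1L]]$dists

  # stage 4: scenarios and thresholds (against the first drug)
  scenarios <- lapply(config$scenarios %||% list(), function(sc) {
    run_scenario(base1, dists1, do.call(scenario_spec, sc),
                 n_iter = config$n_iter, seed = config$seed, wtps = config$wtps)
  })
  if (length(scenarios)) names(scenarios) <- vapply(scenarios, function(s) s$scenario$name, "")
  thresholds <- lapply(config$thresholds %||% list(), function(th) {
    threshold_price(base1, dists1, wtp = th$wtp, target = th$target,
                    n_iter = config$n_iter, seed = config$seed)
  })

  tab2 <- make_table2(psa)
  files <- character()
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(output_dir, x)
    utils::write.csv(tab2, fp("table2.csv"), row.names = FALSE)
    cep <- do.call(rbind, lapply(names(psa), function(drug) {
      do.call(rbind, lapply(names(psa[[drug]]$ce_probability), function(w) {
        ce <- psa[[drug]]$ce_probability[[w]]
        data.frame(comparison = drug, wtp = as.numeric(w), p_ce = ce[["point"]],
                   wilson_lo = ce[["lo"]], wilson_hi = ce[["hi"]])
      }))
    }))
    utils::write.csv(cep, fp("ce_probabilities.csv"), row.names = FALSE)
    writeLines(utils::capture.output(print(cohort_summary)), fp("cohort_summary.txt"))
    if (length(thresholds)) {
      utils::write.csv(data.frame(
        wtp = vapply(thresholds, `[[`, 0, "wtp"),
        target = vapply(thresholds, `[[`, 0, "target"),
        price = vapply(thresholds, `[[`, 0, "price")
      ), fp("thresholds.csv"), row.names = FALSE)
    }
    yaml::write_yaml(list(
      config = config[setdiff(names(config), "output_dir")],
      package_version = as.character(utils::packageVersion("icadcea")),
      r_version = as.character(getRversion()),
      estimated_rrr = est$rrr
    ), fp("provenance.yaml"), precision = 15L)
    files <- list.files(output_dir, full.names = TRUE)
  }

  structure(list(config = config, cohort_summary = cohort_summary,
                 effect_estimate = est, psa = psa, scenarios = scenarios,
                 thresholds = thresholds, table2 = tab2, files = files),
            class = "cea_pipeline")
}

#' @export
print.cea_pipeline <- function(x, ...) {
  cat(sprintf("CEA pipeline: %d drugs, %d iterations, seed %d\n",
              length(x$psa), x$config$n_iter, x$config$seed))
  cat(sprintf("  estimated relative risk reduction: %.1f%%\n",
              100 * x$effect_estimate$rrr))
  print(x$table2[, c("comparison", "incremental_cost", "incremental_qaly",
                     grep("^p_ce_", names(x$table2), value = TRUE))])
  invisible(x)
}
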