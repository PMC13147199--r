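# icadcea

Theoretical cost-effectiveness of PCSK9 inhibitors added to statin therapy
for secondary stroke prevention in severe symptomatic intracranial
atherosclerotic disease (ICAD).

Patients with stroke from 70–99% intracranial stenosis recur at roughly 15%
per year despite aggressive medical management, and attained LDL is one of
the few modifiable predictors. This package asks the health-economic
question: at current and hypothetical prices, is adding a PCSK9 inhibitor
(alirocumab, evolocumab, or inclisiran) to statins good value at standard
US willingness-to-pay thresholds?

The analysis chain:

1. **Synthetic cohort** (`generate_cohort`) — a patient-level population
   emulating the medical arm of a severe-ICAD trial (n = 367, median
   baseline LDL 91 mg/dL, 16.9% recurrent stroke), with event times
   generated from a proportional-hazards law in **log attained LDL** so the
   downstream estimator can be validated against the generator's ground
   truth. No real patient data are distributed.
2. **Evidence synthesis** (`fit_cox`, `project_margins`) — a multivariable
   Cox model of recurrence on log attained LDL, combined with the
   meta-analytic PCSK9i LDL effect (60% reduction, SD 5 points) by
   predictive margins, yielding a relative risk reduction (RRR ≈ 32% under
   the generator defaults).
3. **Markov decision model** (`markov_parameters`, `run_cohort_model`,
   `incremental`) — three states (stable poststroke / recurrent stroke /
   dead), annual cycles, 5-year horizon, 3% discounting, 7%/yr
   discontinuation, RRR applied on the rate scale.
4. **Uncertainty** (`run_psa`, `run_scenario`, `threshold_price`) —
   1000-iteration probabilistic sensitivity analysis with common random
   numbers, Wilson intervals on cost-effectiveness probabilities, scenario
   grid, and bisection threshold-price search.

See `vignettes/methods.Rmd` for model structure, conventions, and the
calibration story.

## Worked example

```r
library(icadcea)

base <- markov_parameters()            # alirocumab at $6600/yr, base case
psa  <- run_psa(base, parameter_distributions(base), n_iter = 1000, seed = 1)
psa
#> PSA: 1000 iterations (seed 1), drug schedule 'alirocumab_dtc'
#>   incremental cost  median $19169 (95% CI 8741 to 32449)
#>   incremental QALYs median 0.183 (IQR 0.122 to 0.238), mean 0.173
#>   P(cost-effective) at $50000/QALY: 7.0% (5.6-8.8)
#>   P(cost-effective) at $120000/QALY: 55.6% (52.5-58.7)

threshold_price(base, parameter_distributions(base),
                wtp = 120000, target = 0.5, n_iter = 1000, seed = 1)
#> Threshold price for 50% cost-effectiveness at $120,000/QALY: $7090/yr
#> (bracket 7070-7109, 12 evaluations)
```

The numbered scripts under `analysis/` run the full narrative
(cohort → synthesis → base-case PSA → scenarios → thresholds), writing CSVs
to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_effect_synthesis.R
Rscript analysis/03_base_case_psa.R
Rscript analysis/04_scenarios.R
Rscript analysis/05_threshold_prices.R
```

`analysis/00_calibrate_costs.R` re-derives the recurrent-state cost
calibration already frozen into the defaults; it only needs re-running if
the calibration target changes.

## Fidelity caveat (read before comparing to the published figures)

The published analysis specifies its parameter distributions in a
supplement that is not publicly available; this implementation fixes the
distribution families a priori (method-of-moments beta for probabilities
and utilities, gamma at 20% CV for costs, truncated normal for the RRR) and
calibrates only what the public record pins down (the median standard-care
cost). Under the frozen conventions the model reproduces the equipoise
price (≈$7,000/yr), the alirocumab and inclisiran CE probabilities, the
incremental-QALY level, and most scenarios within the stated tolerances.

Three published quantities are **not** reproduced, and we believe cannot be
reproduced jointly with the others by any single smooth net-monetary-benefit
model: the evolocumab CE probability (we get ≈48% vs 53.8%; the published
alirocumab→evolocumab drop of 4.8 points over a $600 price gap and
evolocumab→inclisiran drop of 17 points over a comparable effective gap
imply very different NMB spreads), and the 75%/90% threshold prices (we get
≈$5,100/$3,200 vs $3,900/$2,000; prices that low would put the *base case*
far above 50% probability at its own $6,600 price, contradicting the
published 58.6%). The corresponding acceptance tests are left failing
rather than tuned, and the gap is documented where it occurs
(`tests/testthat/test-acceptance.R`).

The Federal Supply Schedule price entries in `builtin_schedules()` are
synthetic placeholders; substitute authoritative values before using them
for anything real.

This is a theoretical exercise on synthetic data. It is not clinical or
pricing advice.
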