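Package: icadcea
Title: Cost-Effectiveness of Add-On LDL-Lowering Therapy for Secondary
    Stroke Prevention in Intracranial Atherosclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic toolkit for evaluating PCSK9 inhibitors added
    to statin therapy in patients with stroke due to high-grade intracranial
    atherosclerotic stenosis. Provides a synthetic patient-level cohort
    generator emulating a secondary-prevention trial population, a two-link
    evidence synthesis (multivariable Cox model of recurrent stroke on
    attained LDL plus predictive-margins projection of a proportional LDL
    reduction), a three-state Markov cohort model of discounted five-year
    costs and quality-adjusted life-years, probabilistic sensitivity
    analysis with Wilson-interval uncertainty on cost-effectiveness
    probabilities, scenario analyses, and threshold (equipoise) drug-price
    search by bisection with common random numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
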