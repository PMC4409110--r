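Package: saltshift
Title: Markov Cohort Modelling and Cost-Utility Analysis of Dietary
    Sodium Reduction Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-state Markov macro-simulation of coronary heart disease
    and stroke in a closed adult cohort, linked to dietary sodium intake
    through the sodium to systolic blood pressure to disease-incidence
    pathway. Implements eight sodium-reduction policy interventions
    (dietary counselling, an endorsement label programme, mandatory
    reformulation of selected or all processed foods, a UK-style package
    and media campaign, a salt excise tax and a supply-side "sinking
    lid"), a generalised cost-effectiveness analysis against a "do
    nothing" comparator (QALYs, net health-system cost, ICERs, per-adult
    cost decomposition), ethnic health-inequality reporting,
    probabilistic sensitivity analysis and tornado diagrams. Because the
    underlying linked administrative health data are not public, the
    package ships a deterministic synthetic-baseline generator that
    reproduces their aggregate structure (age gradients, ethnic rate
    ratios, first-year versus subsequent disease costs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
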