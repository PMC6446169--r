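Package: canncea
Title: Cost-Effectiveness Microsimulation of Adjunctive Smoked Cannabis
    for Chronic Neuropathic Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-patient ("microsimulation") cost-effectiveness model
    of adding smoked cannabis to standard pharmacotherapy for chronic
    neuropathic pain. Simulates treatment-naive patients over 6-week cycles
    through mortality, adherence, adverse-event and pain-relief transitions
    under four strategies (usual care; cannabis added first-, second- or
    third-line), accrues discounted costs (2017 USD, health care sector
    perspective) and quality-adjusted life years, and summarises results as
    an incremental cost-effectiveness frontier with strict and extended
    dominance. Includes one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, scenario analyses
    (alternate horizons, adverse-event odds ratios, cannabis wastage), and a
    YAML-configured, fully seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
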