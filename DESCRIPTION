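Package: cvdmicrosim
Title: Dynamic Microsimulation of Chronic Disease, Healthcare Costs and
    Cardiovascular Prevention Scenarios
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Projects the chronic-disease burden, mortality, healthcare use
    and costs of an adult (30+) population with a discrete-time dynamic
    microsimulation on two-year cycles.  Disease incidence, long-term-care
    admission, smoking changes and death follow complementary log-log
    hazard models; healthcare use follows two-part utilization models with
    a declining structural cost-growth schedule; cardiovascular prevention
    ("incidence") and treatment ("mortality") scenarios are calibrated by
    bisection to a target reduction in the age-standardized death rate of
    people with cardiovascular disease; and outcomes are valued as
    discounted healthcare savings plus the monetary value of life-years
    gained, with bootstrap replication bands.  A synthetic-data generator
    emulates the survey and administrative inputs such models are
    estimated on, so the full pipeline runs without confidential
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
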