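Package: antescreen
Title: Decision-Tree Cost-Effectiveness Model of Antenatal Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing case-finding strategies for
    depression at the first antenatal appointment (Whooley questions, Edinburgh
    Postnatal Depression Scale, Whooley followed by EPDS, and routine midwife
    assessment without an instrument) over a nine-month horizon. Provides the
    deterministic tree evaluation to expected QALYs and costs per woman,
    incremental cost-effectiveness analysis with dominance and extended
    dominance, probabilistic sensitivity analysis with net-monetary-benefit
    cost-effectiveness acceptability curves, a set of thirteen one-way
    sensitivity scenarios, and an individual-level synthetic-cohort
    microsimulation that emulates the source diagnostic-accuracy survey and
    serves as a brute-force check on the analytic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
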