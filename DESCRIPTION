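Package: suppdrive
Title: Suppression-Modification Gene Drive Dynamics and Malaria Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for CRISPR homing gene drives that
    combine population suppression with population modification in Anopheles
    mosquitoes. Provides exact two-locus gamete and offspring distributions
    under germline homing with resistance-allele generation (R1/R2) and a
    trans-acting effector locus; a deterministic infinite-population allele
    frequency recursion; a stochastic discrete-generation simulator of
    laboratory cage-invasion trials with a GFP/PCR screening observation
    model; a daily-timestep stochastic vector-population and Ross-Macdonald
    style malaria transmission model for parameter sweeps over resistance
    rates, mortality multipliers, blood-meal mortality and transmission
    intensity; estimators linking experimental readouts (cross progeny
    counts, survival medians, carrier frequencies, egg output) to model
    parameters; and seeded synthetic-data generators for every readout.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
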