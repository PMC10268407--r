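Package: dectresponse
Title: Tumour Response Criteria Engines and Survival Comparison for
    Dual-Energy CT Iodine Concentration
Version: 0.1.0
Authors@R:
    person("Dect", "Response Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Formal response-criteria engines for longitudinal oncology
    cohorts: RECIST 1.1 sum-of-longest-diameters classification, GCIG CA125
    response and progression rules with nadir tracking and temporal
    confirmation, and a dual-energy CT (DECT) iodine-concentration criterion
    with aortic normalization, a +/-15 percent classification boundary and a
    10/15/20 percent threshold sweep. Derives per-criterion progression-free
    survival, compares responder and non-responder groups with Kaplan-Meier
    curves, log-rank tests and Mantel-Haenszel hazard ratios, cross-tabulates
    criteria in concordance tables, and simulates relapsed ovarian cancer
    cohorts with a latent responder status driving correlated lesion-size,
    iodine, CA125 and time-to-progression trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
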