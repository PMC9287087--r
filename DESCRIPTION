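Package: portalcomp
Title: Energetic Compensation Analysis for Desert Rodent Removal
    Experiments
Version: 0.1.0
Authors@R:
    person("Portal", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the experimental removal of a dominant
    granivore guild (kangaroo rats, Dipodomys spp.) affects desert-rodent
    community-level energy use over decadal time scales.  Converts monthly
    live-trapping capture records into treatment-level energy and biomass
    series via metabolic mass scaling (b = 5.69 * m^0.75), computes
    energetic compensation ((SG_E - SG_C)/KR_C), the exclosure:control
    total-energy ratio, and guild proportional energy use, and compares
    time periods with generalized least squares under continuous-time
    AR(1) errors and quasi-binomial proportion models, including
    estimated marginal means, intervals and Tukey-adjusted contrasts.
    A synthetic community generator with known ground truth makes the
    whole pipeline testable without any field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
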