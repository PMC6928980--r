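Package: noisir
Title: Intermittency Ratio Analysis of Urban Road Traffic Noise
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the eventfulness of road traffic noise from
    1-second A-weighted sound pressure level time series using the
    intermittency ratio (IR), and to classify urban monitoring sites by
    their hourly IR patterns. Provides reading/writing of a 4-column SPL
    monitoring text format, event detection with sound exposure levels,
    hourly IR profiles, robust aggregation to site-by-hour median matrices,
    two-group clustering of sites and hours with a seven-measure validation
    suite (connectivity, silhouette, Dunn, APN, AD, ADM, FOM), classical
    multidimensional scaling, Mann-Whitney ranking of discriminating hours,
    a traffic-flow-based logistic membership model with decision thresholds,
    a physically motivated pass-by simulator for synthetic cohorts, and an
    end-to-end pipeline with CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
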