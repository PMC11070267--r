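Package: dielflux
Title: Diel Timing of High-Altitude Insect Migration from Vertical-Looking Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the diel (24 h) timing of high-altitude insect
    migration from classified vertical-looking radar echoes. Computes solar
    elevation and the four diel phases (crepuscular morning, day, crepuscular
    evening, night) per site and diel day, including the twilight-splitting
    rule for high-latitude summer nights; converts echoes into hourly
    migration traffic rates with monitoring-time and rain rules; derives
    daily proportional migration intensity and traffic; compares sites with
    beta-regression ANOVA (likelihood-ratio omnibus and Holm-corrected
    pairwise post-hoc tests); and summarises radar cross sections and flight
    altitudes by month and diel phase. Includes a seeded synthetic radar-echo
    generator with exported ground truth so every stage of the pipeline can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    utils,
    lubridate,
    readr,
    stats,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
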