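Package: tauflux
Title: Dissolved Free Taurine Release, Flux and Turnover by Crustacean Zooplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for measuring and interpreting the release of
    dissolved free taurine and dissolved free amino acids by crustacean
    mesozooplankton. Covers HPLC method-validation arithmetic (calibration
    linearity, internal-standard quantification, spike recovery, precision,
    detection and quantification limits), biovolume-to-carbon biomass conversion
    for copepods and amphipods, incubation time-series regression with plateau
    truncation and quality-control filtering, scaling of per-individual rates to
    bulk water-column release and steady-state turnover times, and depth-profile
    bookkeeping with nonparametric group comparisons and effect sizes. A seeded
    synthetic-data generator emulates incubation kinetics, depth profiles,
    specimen morphometrics and calibration series so the full pipeline is
    testable without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    jsonlite
Config/testthat/edition: 3
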