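Package: dropnuc
Title: Ultrasound-Driven Vapor-Bubble Nucleation in Elastically Confined
    Perfluorocarbon Nanodroplets
Version: 0.1.0
Authors@R:
    person("dropnuc", "developers", email = "dropnuc@example.org",
           role = c("aut", "cre"))
Description: Modified classical nucleation theory (CNT) for acoustic
    droplet vaporization of perfluoropentane (PFP) nanodroplets embedded
    in elastic tissue. Provides a Redlich-Kwong equation of state with
    liquid-spinodal extraction, metastability-scaled effective surface
    tension, a nucleation-work landscape accounting for droplet
    compressibility and tissue elasticity (critical radius / stable
    critical radius bifurcation), homogeneous nucleation rates and
    probabilities, a self-consistent solver for the initial nucleation
    threshold (INT) at 50% nucleation probability with parameter sweeps,
    and a simplified linear focused-transducer field mapper for
    estimating achievable nucleation areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
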