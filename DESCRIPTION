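Package: synergyci
Title: Median-Effect Dose-Response Fitting and Combination-Index Synergy Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Toolkit", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies drug-combination synergy with the Chou-Talalay
    median-effect framework: MTT plate-reader viability processing,
    log-linear median-effect fitting (Dm, m, r), fixed-ratio combination
    design, combination-index (CI) computation with Fa-CI curves and
    synergy classification bands, plus a synthetic dose-response generator
    with a controllable true CI profile so every stage is testable end to
    end. Includes a fold-change differential screen with a local
    hypergeometric enrichment test and protein-interaction degree ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
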