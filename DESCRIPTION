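Package: synergyrsm
Title: Synergy Combination Modelling for Two-Agent Cytotoxicity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the combined cytotoxic action of two agents
    from plate-based viability assays: median-effect dose-response fitting
    (slope m and median-effect dose Dm, the EC50), two-factor central
    composite designs with quadratic response-surface fitting and
    Design-Expert-style ANOVA diagnostics, Derringer desirability
    optimization of combination concentrations toward a target effect level,
    Chou-Talalay combination-index synergy scoring with CI-Fa curves, and
    blank-corrected, mass-normalized compound-consumption kinetics from
    time-course concentration data. A seeded synthetic-data generator
    emulates the assay structures so the full pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
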