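Package: anaerodesign
Title: In-Silico Design of Micro-Oxic Growth Capability for Obligate
    Aerobic Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based metabolic modelling workflow for converting
    strictly aerobic bacteria into micro-oxic-capable strains. Provides a
    flux balance analysis (FBA) engine over genome-scale stoichiometric
    models, an oxygen-dependent reaction essentiality scan, evaluation of
    heterologous intervention sets (growth-rate prediction under oxic and
    anoxic media), and a comparative core-domainome subtraction between
    facultative-anaerobe and obligate-aerobe genome panels. Ships
    deterministic synthetic-data generators (a toy metabolic network with
    planted oxygen-dependent essential reactions and an ATP-limited
    anaerobic mode, and protein-domain annotation tables with a planted
    group-exclusive core) so every stage runs and is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
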