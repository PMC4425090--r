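Package: greenextract
Title: Solvent Substitution Screening for Vegetable-Oil Extraction
Version: 0.9.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating bio-based replacement solvents for
    hexane in oilseed solid-liquid extraction. Implements Hansen
    solubility parameter (HSP) screening with inverse solubility-sphere
    fitting from relative energy difference (RED) panels, Crank
    sphere-diffusion extraction kinetics (forward simulation and
    fitting of effective diffusivity and starting accessibility),
    multi-wash percolation simulation, an energy and steam ledger for
    the oilseed crushing process, a techno-economic balance of solvent
    substitution, fatty-acid/sterol/tocopherol composition summaries,
    and synthetic-data generators emulating bench kinetics and
    composition replicates. Ships the property and observation tables
    for n-hexane and 2-methyltetrahydrofuran (MeTHF) as plain-text
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
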