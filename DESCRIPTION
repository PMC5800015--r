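Package: carecascade
Title: Filter-Cascade Cost-Effectiveness Modelling for Care Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic multi-stage ("filter") cascade model for
    care pathways, developed around depression care in cancer settings.
    A target population flows through an ordered sequence of filters
    (e.g. detection, provider response, patient acceptance, treatment),
    each with a pass rate and a per-entrant unit cost. The package
    evaluates expected patient flows and costs per scenario, compares
    intervention scenarios to a baseline (incremental cost, incremental
    successes, incremental cost-effectiveness ratio, policy advice on the
    cost-effectiveness plane), and performs one-way deterministic
    sensitivity analyses including tornado ordering and threshold
    solving for a target ICER. Scenario configurations are read from and
    written to YAML or JSON, and results can be rendered as comparison
    tables or exported as CSV/JSON. A command-line interface exposes the
    whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
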