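Package: chemfunnel
Title: Design and Profiling of Diverse Screening Compound Libraries
Version: 0.1.0
Authors@R:
    person("DDU", "Library Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for designing diversity screening libraries from
    combinatorial building-block chemistry: basis-set and capped super-set
    enumeration from two-component reactions, SMARTS structural-alert (PAINS,
    reactive/toxic) filtering, staged lead-like physicochemical windows
    including the Solubility Forecast Index, MaxMin diverse-subset selection
    on Morgan fingerprints with redundancy-driven per-sublibrary quotas,
    Tanimoto novelty filtering against exclusion sets, Bemis-Murcko scaffold
    and framework uniqueness analytics, PCA/t-SNE chemical-space comparison,
    and an auditable end-to-end selection funnel with composition targets.
    Chemistry primitives are computed by a bundled RDKit bridge run through a
    system Python interpreter.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.9) with rdkit, numpy and scikit-learn on the
    interpreter found by Sys.which("python") (override via
    options(chemfunnel.python = ...)).
Config/testthat/edition: 3
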