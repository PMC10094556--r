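Package: pathsar
Title: Path Analysis of Structure-Activity Relationships for
    Compositional Mixtures
Version: 0.1.0
Authors@R:
    person("pathsar", "maintainers", email = "pathsar@example.org",
           role = c("aut", "cre"))
Description: Decomposes the total correlation between each component of a
    compositional mixture (e.g., proanthocyanidin monomer units) and a
    measured bioactivity into a direct effect and indirect effects routed
    through correlated components, using Wright-style path analysis: the
    standardized multiple regression whose canonical equations are
    Rxx b* = Rxy. Provides significance gating (F test), importance
    ranking, influence-mode classification, importance categories,
    cross-activity comparison, reconstruction of correlation structures
    from published decomposition tables, synthetic data generation with
    known ground truth, path-chart construction with banded correlation
    edges (DOT/GraphML export), and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
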