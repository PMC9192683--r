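Package: incidiv
Title: Incidence-Based Hill-Number Diversity Estimation for Benthic Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of sessile-invertebrate diversity across
    benthic habitats from phenotype-by-sampling-unit incidence data. Implements
    the four-step Hill-number workflow (sample-completeness profiles, size-based
    rarefaction/extrapolation, coverage standardization at C_max, and evenness
    profiles with Pielou's J), incidence-frequency Chao2 richness and asymptotic
    Shannon/Simpson estimators with an incidence bootstrap for confidence bands,
    classical Shannon/Simpson/evenness indices for cross-study comparison,
    Bray-Curtis community-composition tests (PERMANOVA, multivariate dispersion,
    nMDS, Venn partitioning), surface-area enlargement factors for algal mat,
    seagrass and hard-bottom substrates, and a synthetic multi-habitat
    assemblage generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
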