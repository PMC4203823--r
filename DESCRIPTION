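Package: bgctyper
Title: Biogeochemical Typing of Multi-Omics Community and Chemical Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Extracts biogeochemical (BGC) types from paired microbial
    community and chemical-profile tables observed over the same sampling
    points.  OTU count tables (Archaea, 16S and 18S rRNA amplicons) are
    singleton-filtered, normalized to relative abundances and fused into a
    community matrix; element concentrations, FT-IR region integrals and
    1H-NMR bucket integrals are fused into a chemicals matrix.  OTUs whose
    abundance fluctuations track chemical variables (Spearman |rho| at or
    above a threshold) are organized into BGC types by principal component
    analysis and k-means clustering, with the number of types chosen from
    the within-cluster sum-of-squares curve.  Each type is described by its
    community distribution over sampling points, a class-level taxonomy
    breakdown, and an extracted chemical profile based on average
    correlations, PCA loadings and population standard deviations.  A
    synthetic-data generator with planted OTU-chemical association blocks
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    biomformat,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
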