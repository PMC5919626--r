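Package: shapeselect
Title: Comparative Quantitative Genetics of Protein Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats protein structures as landmark shapes (one 3-D
    residue centroid per homologous site) and applies the comparative
    quantitative genetics toolkit to ensembles of homologous structures.
    Multi-model PDB ensembles (molecular-dynamics snapshots or NMR
    models) are abstracted into a phenotype matrix via Generalized
    Procrustes superimposition; the phenotypic covariance is decomposed
    into a pooled-within-structure ("dynamic") component and a
    between-structure component that serves as a proxy for the additive
    genetic (G) matrix. On top of the decomposition the package computes
    multivariate breeder's-equation responses, selection and dynamic
    gradients, evolutionary-constraint angles, per-residue gradient maps
    and residue rankings under a user-supplied fitness (by default a
    per-residue unfolding-energy proxy), compares covariance matrices by
    Cheverud's random-skewers test, and ships a synthetic grouped-shape
    simulator with known generating matrices for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    MASS,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
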