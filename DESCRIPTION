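Package: famnet
Title: Spatial Familial Networks from Multilocus Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs parent-offspring pedigrees from multilocus
    microsatellite genotypes and analyses them as directed familial
    networks. Provides sample consolidation and genotyping quality
    control (allelic dropout and false-allele rates), exclusion plus
    likelihood parentage assignment with inferred unsampled parents,
    network construction with node centrality profiles (alpha,
    betweenness, harmonic closeness, degree, eccentricity), edge
    betweenness distributions with Girvan-Newman style edge removal,
    and spatial local-area cohesion reports (edge-to-node ratios,
    first-neighbor expansion). Includes a spatial population simulator
    with known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
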