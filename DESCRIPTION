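Package: dendropart
Title: Metacommunity Variation Partitioning on Dendritic Stream Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for eigenfunction-based spatial analysis of stream
    metacommunities. Builds dendritic stream-network data structures and the
    distance matrices they support (overland and watercourse geographical,
    altitudinal and glaciality distances), derives a glaciality index from
    harshness variables by non-centred principal component analysis,
    constructs Moran's eigenvector maps (MEM/PCNM) and asymmetric eigenvector
    maps (AEM) as spatial predictors, and partitions Hellinger-transformed
    community variation among environmental and spatial predictor blocks with
    adjusted R-squared redundancy analysis, permutation tests and forward
    selection with the double stopping criterion. Includes a seeded synthetic
    data generator for glacierized catchments so every stage can be exercised
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vegan
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
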