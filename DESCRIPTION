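Package: carenets
Title: Healthcare Provider Patient-Sharing Networks and Quality of Care for
    Severe Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds index-hospital-centered, patient-sharing provider networks
    from claims-like tables for adults hospitalized with severe mental health
    disorders, characterizes each network (density, transitivity, weighted
    degree, composition, loyalty index, contact intensity), derives a typology
    of networks by hierarchical clustering on principal components with a
    three-method robustness check, computes four utilization-based quality
    indicators on the schizophrenia-spectrum subcohort, and relates quality to
    network characteristics with cluster-correlated log-binomial generalized
    estimating equations. Includes a synthetic claims generator with planted
    network archetypes and planted outcome effects so that every stage of the
    pipeline can be validated end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    mclust,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
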