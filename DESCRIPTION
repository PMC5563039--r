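Package: metapot
Title: Community Metabolite Potential Modeling for Microbiome-Metabolome Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates predicted metagenome functional profiles with untargeted
    metabolomics through community-wide metabolite potential (CMP) scores.
    Builds a row-normalized stoichiometric matrix from an irreversible reaction
    network linking gene families (KEGG Orthology style) to compounds,
    multiplies it with per-sample gene-family abundances to obtain per-compound
    metabolite-potential scores, classifies metabolites as well predicted by a
    Mantel permutation test with a permutation-null (bootstrap) estimate of the
    false discovery rate, and deconvolves community scores into per-taxon
    contributions to identify key contributor phylotypes. Also provides the
    supporting preprocessing steps (OTU low-abundance filtering, rarefaction,
    hypergeometric class enrichment), accurate-mass annotation of LC-MS
    features with proton-adduct arithmetic and ppm tolerance search, and a
    synthetic-study generator with planted metabolite-potential couplings for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vegan,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
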