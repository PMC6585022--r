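Package: paralogon
Title: Relative Dating and Topology Congruence of Gene Family Duplications
    on the Human Hsa 1/2/8/20 Paralogon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing block-duplication hypotheses (including the 2R
    whole-genome-duplication hypothesis) on human paralogy regions.  Provides
    neighbor-joining tree inference from trimmed protein alignments with
    bootstrap support, species-overlap detection of gene duplication nodes,
    ordinal dating of duplications into speciation-bounded epochs on a
    reference metazoan species tree, and translocation-aware congruence
    clustering of chromosome-labelled schematic topologies into co-duplicated
    groups.  A duplication-history simulator generates gene families with
    known event placements so the whole pipeline can be exercised end to end.
    Ships a catalog of human gene families with three- or four-fold
    representation on chromosomes 1, 2, 8 and 20.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
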