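Package: phylosieve
Title: Gene Screening, Supermatrix Curation and Topology Robustness for
    Phylogenomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for curating phylogenomic supermatrices and assessing the
    robustness of deep phylogenetic splits. Implements per-gene quality
    screening (long-branch outlier detection, anomalous-grouping and paralogy
    flagging with whitelist-aware keep/drop rules), partitioned supermatrix
    assembly with taxon- and site-occupancy filters, a discrete-gamma
    amino-acid likelihood engine for per-site rate categorisation and
    fast-site stripping, quartet-frequency internode certainty with an
    exhaustive enumeration mode, and the approximately unbiased (AU) topology
    test via multiscale RELL bootstrap. A seeded sequence simulator with
    artifact injection (paralogs, contaminants, elongated terminal branches,
    masked taxa) provides ground-truth data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Phylogenetics, Software, Alignment
RoxygenNote: 7.3.3
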