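Package: phenoprio
Title: Evaluating Disease Phenotype Networks for Network-Propagation Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking disease phenotype similarity networks as
    prior knowledge in protein-protein interaction (PPI) based gene
    prioritization. Provides symmetrization, range normalization (Lin, Sqrt,
    Maxmin, Tanimoto) and logistic calibration of disease-disease similarity
    matrices; PRINCE-style label propagation over a degree-normalized PPI
    network with a closed-form oracle; leave-one-out cross-validation over
    disease-gene associations for monogenic and polygenic diseases with mean
    rank ratio, top-ranking counts and TPR@k statistics; network integration
    at arbitrary mixing proportions and a logistic steepness parameter sweep;
    and a synthetic-data generator that plants the guilt-by-association
    structure (phenotypically similar diseases mapping to PPI-proximal genes)
    so the whole pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
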