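Package: txconn
Title: Connectome-Transcriptome Association Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("txconn", "maintainers", email = "maintainers@txconn.dev",
    role = c("aut", "cre"))
Description: Tools for linking group differences in resting-state functional
    connectivity (FC) to regional gene expression. Builds Fisher-z FC matrices
    from regional time series, harmonizes multi-site effects with empirical-Bayes
    ComBat while protecting biological covariates, tests group contrasts at the
    edge and network level with network-based statistics (NBS) permutation
    correction, summarizes each region by its net t-value, regresses the
    regional map on microarray-style gene expression with SIMPLS partial least
    squares, assesses significance with variogram-matched spatially
    autocorrelated surrogate maps, scores genes by bootstrap z-scores, and runs
    hypergeometric over-representation analysis with Benjamini-Hochberg FDR on
    GMT gene-set collections. Includes a fully seeded synthetic-data generator
    (atlas, multi-site two-group cohorts, donor expression tables, gene sets)
    emulating the statistical structure such studies assume, plus an
    end-to-end pipeline driver and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
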