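Package: hubcent
Title: Eigenvector Centrality Mapping and Component-Based Analysis of
    Brain Network Hubs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-wise eigenvector centrality mapping (ECM) of fMRI runs
    over the absolute full-correlation graph, spatial ICA decomposition of
    centrality maps with per-run subject weights, dual-regression extraction
    of component time series with block-design n-back GLMs, component-wise
    statistics (task effects, age and performance associations, BH-FDR), and
    voxel-wise permutation inference with threshold-free cluster enhancement.
    Includes a synthetic multi-subject cohort generator with planted network,
    task, age and behaviour effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
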