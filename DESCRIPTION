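Package: rsnconn
Title: Three-Level Resting-State Network Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing resting-state network (RSN) functional
    connectivity between a patient and a control group from region-of-interest
    (ROI) fMRI time series. Pearson ROI-pair correlations are mapped to a
    positive similarity through an exponential transform of the hyperbolic
    correlation distance, then summarized at three levels: nodal integration
    (total transformed connectivity per ROI), intra- and inter-network
    composite scores, and edge-wise network-based statistic (NBS) inference
    with permutation control of the family-wise error rate. Group comparisons
    of nodal and network measures use covariate-adjusted Freedman-Lane
    permutation tests with Benjamini-Hochberg false discovery rate control;
    brain-behavior associations use Spearman correlation after outlier
    removal. A synthetic-study generator produces two-group ROI time series
    with block-correlation network structure, planted group effects, head
    motion summaries and coupled cognitive scores, so that every stage of the
    pipeline can be validated without clinical data. Includes head-motion
    quality control (frame-wise displacement) and the standard demographic
    comparison tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
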