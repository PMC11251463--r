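Package: cogphen
Title: Cognitive Phenotype Discovery and MRI Network Metrics for Pediatric
    Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for data-driven cognitive phenotyping of
    pediatric multiple sclerosis cohorts. Discovers cognitive phenotypes by
    K-means clustering of neuropsychological test z-scores with majority-vote
    consensus selection of the cluster number over a panel of cluster-validity
    indices; normalizes MRI metrics against scanner-matched healthy controls;
    scores lesion-induced structural disconnection (change-in-connectivity,
    the proportion of reference streamlines passing through lesioned tissue)
    within cortical networks; computes resting-state functional-connectivity
    weighted degree within cortical networks; and compares groups with
    covariate-adjusted linear models, estimated marginal means, and
    Benjamini-Hochberg false-discovery-rate correction. Ships a synthetic-data
    generator (cognitive cohorts with planted phenotypes, healthy-control
    references, toy lesion/streamline worlds, ROI BOLD series) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    emmeans,
    RNifti,
    optparse
Config/testthat/edition: 3
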