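Package: fibersets
Title: Multi-Subject White-Matter Fiber Clustering with Dominant Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage clustering of diffusion-MRI tractography streamlines.
    Stage one segments each subject's tractogram into white-matter bundles by
    extracting dominant sets from a fiber affinity graph via replicator
    dynamics, prunes weak clusters using cohesiveness statistics, and keeps a
    medoid streamline per bundle. Stage two matches bundles across subjects
    without any spatial registration: medoids are encoded by their distances
    to anatomical landmark points, a block affinity matrix with zeroed
    intra-subject blocks is clustered with the same dominant-set machinery,
    and clusters spanning every subject are retained. Includes streamline
    resampling and distance metrics, a seeded synthetic tractography cohort
    generator with ground-truth bundle labels, clustering evaluation indices
    (adjusted Rand index, completeness), TCK and CSV streamline input/output,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
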