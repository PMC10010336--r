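Package: wpcna
Title: Weighted Protein Coexpression Network Analysis with Consensus
    Clustering and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed weighted coexpression networks from quantitative
    proteomics abundance matrices (robust biweight midcorrelation,
    soft-threshold selection by scale-free topology fit, topological overlap,
    dynamic dendrogram cutting, module merging), characterizes the resulting
    protein modules (module eigenproteins, kME module membership, intramodular
    hubs, module-trait association, module graphs), stratifies samples by
    subsampled k-means consensus clustering on module signatures, and relates
    the strata to overall survival (Kaplan-Meier, log-rank, Cox proportional
    hazards). Includes TMT-style ratio normalization, variance-based feature
    selection, Wilcoxon differential expression with Benjamini-Hochberg
    adjustment, hypergeometric gene-set over-representation, and a synthetic
    data generator with planted module, group, batch and survival structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    igraph,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
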