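Package: salpop
Title: Population Coding Analysis of Salient Distractors During Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how search targets and salient ("singleton")
    distractors are encoded by neural populations recorded during visual
    search. Provides a synthetic spike-train generator with planted ground
    truth (temporal-selectivity archetypes, location tuning, controllable
    target/singleton subspace overlap), spike-density estimation and saccade
    detection, per-unit selectivity statistics (modulation index,
    criterion-sweep AUROC with permutation nulls and FDR, omega-squared
    percent explained variance with permutation z-scoring, latency
    estimation), graph-based clustering of temporal selectivity profiles
    (k-nearest-neighbour Jaccard graph with Louvain modularity maximisation),
    pseudo-population decoding with a linear support vector machine and
    cluster-based permutation inference, and Stiefel-manifold optimisation of
    orthogonal, exclusive and shared low-dimensional subspaces for target and
    distractor location coding, with alignment indices and per-unit weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
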