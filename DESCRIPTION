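Package: phyniche
Title: Phylogenetic Comparative Analysis of Climatic-Niche Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative-methods pipeline for characterizing the evolution
    of climatic niches on time-scaled phylogenies. Computes Blomberg's K with
    accession-level sampling error folded in via pooled variances, disparity
    through time with the MDI statistic and a Brownian-motion simulation
    test, maximum-likelihood fits of Brownian motion, Ornstein-Uhlenbeck and
    early-burst trait-evolution models compared by AICc weights, and absolute
    per-tip rates of niche change from ancestral state reconstruction on
    model-transformed covariances. All analyses run on a maximum clade
    credibility tree plus a posterior tree ensemble, with highest posterior
    density summaries across trees, and include a synthetic-data generator
    that emulates accession-level bioclimatic sampling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
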