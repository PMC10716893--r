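Package: molgrow
Title: Molecular Generation by Graph Variational Auto-Encoding and Monte
    Carlo Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grows drug-like molecules atom by atom. A variational graph
    auto-encoder is trained on molecular graphs of known compounds; decoded
    node and edge feature maps then guide a Monte Carlo tree search (UCB1
    selection, valence-protected expansion, random rollouts) that optimizes
    quantitative drug-likeness (QED) or penalized logP, with aromatic-ring
    seeding and chemical-realism filters. Includes distribution-learning
    evaluation (validity, uniqueness, novelty, KL-divergence score),
    Mann-Whitney tests with Bonferroni correction, drug-likeness filtering,
    circular-fingerprint chemical-space maps, a seeded fixture-molecule
    generator, and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
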