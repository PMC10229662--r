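Package: retrosynth
Title: Two-Step Graph-Based One-Step Retrosynthesis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semi-template one-step retrosynthesis prediction on molecular
    graphs. Given a target product, a message-passing graph encoder scores
    typed reaction centers (newly formed bonds, bonds with changed order,
    and atoms losing a fragment), the product is split into synthons by
    reversing the center edit, and synthons are completed into ranked
    candidate reactant sets by sequentially attaching bond and ring
    substructures mined from training reactions. Includes teacher-forced
    training of both modules, greedy beam-search inference scored by summed
    log-likelihoods, top-k accuracy and reaction-similarity/diversity
    evaluation, a USPTO-style reaction reader, and a synthetic reaction
    generator with known ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
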