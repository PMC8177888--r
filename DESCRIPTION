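Package: larvaconn
Title: Sensory-to-Neuroendocrine Connectome Analysis for the Drosophila Larva
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synapse-resolution connectivity between
    sensory neurons, interneurons and ring gland projection neurons (RPNs,
    the neurosecretory output cells) of the Drosophila larva. Provides a
    typed connectome data model with CSV input/output and input-fraction
    weight normalisation, thresholded upstream-partner and 1-/2-hop pathway
    analysis, sensory-profile summaries, hive-plot edge tables, a
    feed-forward network (FFN) diffusion model that predicts neurosecretory
    activation from sensory drive through a rectified linear-ramp activation,
    sensory-to-endocrine hub scores, dense-core-vesicle target-tissue
    fractions, and a seeded synthetic-connectome generator with plantable
    sensory-to-endocrine pathway motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
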