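Package: semdec
Title: Semantic Decoding of Brain Activation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decoding distributed semantic representations from
    functional MRI activation patterns. Builds a semantic space from word
    embeddings and samples it by spectral clustering; trains per-dimension
    ridge regression decoders with the regularization strength chosen by
    generalized cross-validation; selects informative voxels by the
    cross-validated predictive score of each voxel together with its 26
    three-dimensional neighbors; and evaluates decoded vectors with pairwise
    classification, rank accuracy, and open-vocabulary word-spotting
    statistics under their respective null models. Includes a synthetic-data
    generator implementing a linear forward model from semantic vectors to
    voxel activations, so that every pipeline stage can be validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
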