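Package: lcdrops
Title: Machine-Learning Analysis of Liquid-Crystal Droplet Micrographs for
    Trace Amphiphile Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting trace amphiphilic contaminants (PFOA, PFOS
    and their mixtures) from cross-polarized micrographs of nematic
    liquid-crystal droplet arrays. Provides a seeded synthetic micrograph
    generator with ground-truth labels and a tunable class effect size,
    Canny-based droplet detection and cropping with distribution-determined
    size cutoffs, 20-fold affine augmentation, a jointly trained
    convolutional autoencoder and classifier with an EMA-normalized combined
    loss, stratified 5-fold cross-validated evaluation with macro-F1
    reporting, transfer learning via a frozen encoder, and latent-space PCA
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
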