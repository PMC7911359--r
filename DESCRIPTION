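Package: tcsdca
Title: Coevolutionary Specificity Scoring for Bacterial Two-Component
    Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers Potts-model couplings and local fields from paired
    histidine-kinase/response-regulator domain alignments by mean-field
    Direct Coupling Analysis, and scores interaction specificity of every
    HK-RR combination with an interface-masked Hamiltonian referenced
    against a scrambled-pairing null model. Includes in-silico mutation
    rescoring of whole specificity networks, positive/negative-selection
    classification of cognate pairs, a planted-coupling synthetic
    alignment generator for end-to-end validation, and CSV/PNG export of
    specificity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
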