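Package: emomediate
Title: Emotional Mediation Analysis of Music-to-Color Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether cross-modal music-to-color
    associations are mediated by shared emotional content. Implements
    weighted best/worst music-color association (MCA) scoring, joint
    three-mode Parafac (CANDECOMP/PARAFAC) factor extraction of
    arousal and valence by multi-start alternating least squares with
    the core consistency diagnostic, rank-based partial-correlation
    mediation tests with family-wise error control, inter-rater
    reliability, and hierarchical variance partitioning. Includes a
    synthetic study-bundle generator with planted latent affect
    structure and switchable mediated/direct choice regimes, so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'data_io.R'
    'emomediate-package.R'
    'mca.R'
    'parafac.R'
    'stats.R'
    'pipeline.R'
    'synthetic.R'
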