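Package: synaptoglia
Title: Quantification of Microglial Synaptic Engulfment, Dendritic Spines,
    Synaptic Currents, and Social Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, fully tested implementation of the bespoke
    quantification pipelines used to link complement C4 overexpression in
    developing mouse prefrontal cortex to microglial engulfment of
    postsynaptic material, dendritic spine loss, weakened synaptic drive,
    and social behavior deficits. Provides confocal colocalization and
    triple-channel (PSD-95/Iba1/CD68) engulfment scoring with a
    pixel-shift chance-colocalization null, expansion-microscopy scaling
    and lysosome analysis, brightness-based (TIB) dendritic spine
    classification, miniature postsynaptic current detection and passive
    membrane property estimation, rodent zone-occupancy behavior metrics,
    neuronal morphometry (Sholl), and multi-reference qPCR relative
    expression. A ground-truthed synthetic-data generator emulates every
    input modality so each stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
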