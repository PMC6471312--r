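Package: sinterOCT
Title: Quantitative Sintering Assessment of Dental Ceramics from En-Face OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect loss of calibration of dental sintering ovens
    from en-face (constant-depth) optical coherence tomography images of
    ceramic prostheses. Implements reflectivity-profile extraction by
    y-line averaging, binarization and 8-connected grain counting,
    piecewise vertex-constrained parabolic modeling of the averaged
    reflectivity graph, a multi-parameter characterization (extremes,
    differences, ratios, maximum gradient and curvature), and a rule-based
    firing-temperature verdict (under-fired / normal / over-fired). A
    seeded synthetic phantom generator emulates the reflectivity archetypes
    of the study groups so that every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assessment.R'
    'fit.R'
    'groups.R'
    'io.R'
    'model.R'
    'parameters.R'
    'pipeline.R'
    'profile.R'
    'synthetic.R'
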