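Package: cochleaR
Title: Cochlear Spiral Canal Length Measurement with Quantized Chord Rulers
Version: 0.1.0
Authors@R:
    person("cochleaR", "Maintainers", email = "maintainers@cochlear-morphometry.org",
           role = c("aut", "cre"))
Description: Measures the length of the cochlear spiral canal on 3D volumetric
    images by walking an extracted vestibule-to-apex centerline with predefined
    digitized rulers (2.0, 1.5 and 1.0 mm chords) and summing the placed
    segments. Provides a parametric helico-spiral phantom generator with known
    ground-truth arc length, canal segmentation and centerline extraction by
    3D thinning and shortest-path tracing, chord-versus-arc underestimation
    analysis, MetaImage volume I/O, plain-text centerline and segment-table
    formats, and the six-case reference measurement tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
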