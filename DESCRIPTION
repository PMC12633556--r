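Package: retwave
Title: Detection and Spatiotemporal Analysis of Retinal Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automatic detection of retinal waves from spatiotemporally
    resolved neural-activity recordings (high-density multielectrode-array
    spike data or calcium-imaging movies). Spike events are rasterized onto
    the electrode grid, tonic firing is removed by a dynamic per-pixel burst
    filter, and waves are segmented as maximal clusters of phasic pixels
    connected in space (x, y) and time (t) by a 3D flood fill. Per-wave
    spatiotemporal properties are quantified: frequency, inter-wave
    intervals, area, duration, wavefront speed via the Euclidean distance
    transform, initiation site and initiation bias, flow field and
    propagation-direction bias, and a local synchrony index. A synthetic
    recording generator with ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
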