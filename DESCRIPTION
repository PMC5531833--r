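Package: ciliomotor
Title: Analysis of Whole-Body Ciliomotor Circuits, Calcium Imaging and
    Ciliary Activity in Ciliated Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the neuronal control of whole-body ciliary
    swimming in planktonic larvae. Builds synapse-count-weighted connectome
    graphs of ciliomotor neurons and multiciliated cells, applies the
    at-least-five-synapses ciliomotor inclusion rule, computes group-wise
    connectivity matrices, detects network modules by resolution-scaled
    weighted modularity maximisation, and measures smoothed neurite cable
    length from SWC skeletons. Processes calcium-imaging movies and traces:
    rigid motion correction, minimum-variance-window baseline estimation,
    dF/F0 transforms, pixel-wise Pearson correlation maps, and Fourier
    cycle-length analysis. Quantifies ciliary activity from kymographs:
    arrest-interval detection, beat frequency, arrest rates, inter-band
    resumption delays, and the association between ciliary arrest and the
    calcium derivative. A synthetic-data generator with the two-phase
    stop-and-go pacemaker structure provides ground truth for every stage,
    so the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
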