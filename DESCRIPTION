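Package: vncactivity
Title: Two-Photon Calcium Imaging Analysis for the Fly Ventral Nerve Cord
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (GCaMP6s activity plus
    tdTomato structural) two-photon imaging of ventral nerve cord neurons
    in behaving flies on a spherical treadmill. Provides non-rigid
    variational motion correction solved by ADMM with a sparse
    feature-matching constraint and divergence-based artifact rejection;
    optic-flow-based behavior quantification (velocity conversion, bout
    segmentation, video annotation of walking and grooming); pixel-wise
    behavior-regression maps built from a calcium impulse response;
    ROI detection, tracking and ratiometric signal extraction; and
    fluorescence transient event detection with bilateral reconciliation,
    event-triggered summaries, bootstrapped confidence intervals and
    time-shuffled controls. A synthetic-data generator with known ground
    truth (deformation fields, planted transients, behavior schedules)
    makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Regression, Preprocessing
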