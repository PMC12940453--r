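Package: vibramp
Title: Micrometre-Scale Vibration Analysis from High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Visualizes and quantifies micrometre-scale vibrations recorded on
    high-speed video, as used for mechanical quality assurance of MRI scanners
    during diffusion-weighted acquisitions. Implements Eulerian video
    magnification (ideal temporal bandpass on a Laplacian image pyramid),
    sub-pixel tracking of cross-shaped fiducial markers by normalized
    cross-correlation with paraboloid refinement, conversion of tracks to
    physical displacement via pixel-pitch calibration and the motion gain of
    the amplification, RMS/peak-to-peak displacement metrics, combined X/Y
    amplitude spectra, split-half Bland-Altman stability analysis, and
    block-bootstrap/permutation inference for idle-versus-scanning contrasts.
    A synthetic scene generator renders cross markers under known sub-pixel
    multi-tone motion with exact ground truth, so the whole pipeline is
    testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'scene-sim.R'
    'magnify.R'
    'track.R'
    'quantify.R'
    'spectra.R'
    'stats.R'
    'io.R'
    'pipeline.R'
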