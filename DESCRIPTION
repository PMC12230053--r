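Package: leafshape
Title: Camera-Based Leaf Shape Quantification and Canopy Light Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying maize (Zea mays) leaf shape from conveyor-belt
    video recordings and for simulating the consequences of leaf shape for canopy
    light interception. Implements a computer-vision pipeline that assembles a full
    leaf image from moving-belt frames, calibrates pixels to centimetres via a
    circular reference marker, and measures leaf width per segment from outer
    contours while ignoring interior defects; a sine-based leaf-shape model with
    bounded nonlinear least-squares fitting, leaf-area-coefficient integration and
    width-adjustment identities that hold leaf area constant across shapes; a
    synthetic-data generator (leaves, conveyor videos, weather series) with known
    ground truth; and a functional-structural canopy model with thermal-time
    development, sigmoid organ expansion and Monte-Carlo ray-traced light
    interception over an hourly direct plus 72-source diffuse sky.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
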