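Package: perclos
Title: Driver Fatigue Detection from Facial Landmark Streams with
    Time-Accumulation Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects driver drowsiness from per-frame 68-point facial
    landmark streams. Computes per-frame eye and mouth openness (eye
    aspect ratio, including an image-processing variant based on Otsu
    binarization of the eye region, and mouth aspect ratio), aggregates
    them over sliding time windows into three fatigue features (longest
    continuous eye closure, yawn count, PERCLOS), classifies windows
    with a small feed-forward neural network, and filters transient
    expression noise (smiles, speech) with a sigmoid-weighted
    time-accumulation model over window segments. Includes a Kalman
    filter for face bounding-box tracking through detection failures
    and a synthetic scenario generator for landmark streams, rendered
    eye images, and labelled training windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
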