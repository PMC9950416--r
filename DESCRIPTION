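Package: rungwalk
Title: Analysis Pipeline for a Dynamic Obstacle-Course Locomotion Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze rodent locomotion over a reconfigurable
    obstacle course with switchable (stable/unstable) steps: nose and body
    tracking from side-view video via background subtraction and connected
    component labeling, region-of-interest activation traces, crossing and
    paw-contact event detection with a head-position plausibility constraint,
    slip candidate screening and semi-automated confirmation, posture and
    speed-profile statistics (speedup index, jumper classification,
    history-conditioned posture), ethogram-based response contingency
    statistics (chi-square with Yates correction, pooled-summary t-tests),
    frame-synchronized electrocorticography evoked-potential extraction, and
    serial-section lesion volumetry. A synthetic-data generator emulates the
    rig (rendered crossings, ROI traces, strobe-synchronized ECoG, lesion
    phantoms) with known ground truth so the whole pipeline can be exercised
    end to end without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
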