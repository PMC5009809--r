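Package: TrackContacts
Title: Detection and Timing of Dendritic Cell-NK Cell Interactions in 3D
    Cell-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and times cell-cell interaction events in 3D
    cell-tracking data from two-photon lymph-node imaging. Implements a
    user-independent three-criterion detector (centroid distance, speed
    relative to the field-of-view average, and non-increasing confinement
    ratio) that segments NK-cell/dendritic-cell contacts into maximal
    qualifying frame runs with a single-frame, single-parameter tolerance,
    classifies them as touch-and-go, intermediate or long interactions,
    and aggregates cohort statistics (fraction of interacting cells,
    long-interaction fraction, duration and 3D-velocity distributions,
    between-condition t-tests). A persistent-random-walk simulator with
    planted contact episodes and full ground truth supports end-to-end
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'motility.R'
    'detection.R'
    'cohort.R'
    'simulate.R'
    'reporting.R'
    'track-io.R'
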