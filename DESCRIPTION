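Package: vtcwm
Title: White-Matter Connectivity Profiles of Ventral Temporal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the white-matter connections of functionally
    defined regions in human ventral temporal cortex from streamline
    tractography. Extracts functional sub-bundles from a tractogram by radial
    search around surface regions of interest, builds endpoint-density
    connectivity profiles over a cortical parcellation, classifies
    cytoarchitecture, category-selectivity and age group from profiles with
    leave-one-subject-out multinomial regression, quantifies connections to
    eccentricity bands in early visual cortex, and measures developmental
    change of connectivity with bootstrap slope-similarity analysis. Includes
    a synthetic cohort generator (meshes, labels, session tables and
    tractograms with planted statistical structure) so the full pipeline can
    be exercised and validated without MRI data, plus MRtrix track-file and
    PLY surface I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
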