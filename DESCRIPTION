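Package: ednadyn
Title: Dynamic Co-Occurrence Inference from eDNA qPCR Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring predator-prey interaction dynamics from
    replicate-level environmental DNA (eDNA) qPCR surveys of pond communities.
    Fits qPCR standard curves (amplification efficiency, limit of detection and
    quantification), scores site-month detections from biological and technical
    replicates, encodes month-to-month occupancy transitions (stay-zero,
    persist, enter, disappear), builds row-conditional co-occurrence matrices
    over transition events, and tests them against a Monte-Carlo permutation
    null that shuffles each species' transitions across sites. Includes a
    multi-season occupancy simulator with a configurable predator-prey
    interaction and an overlaid qPCR observation layer, so the whole inference
    chain can be validated without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
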