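Package: fruitmot
Title: Fruit Counting in Orchard Videos by Improved Multi-Object Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection pipeline for counting fruit in video surveys
    of orchard rows. Links per-frame detector output into fruit identities with a
    constant-velocity Kalman filter, Mahalanobis-gated appearance cascade matching
    and Hungarian assignment, adds an appearance-only re-matching stage that
    recovers tracks lost to sudden motion changes, and an offline track-segment
    merging step that removes duplicate identities caused by occlusion. Fruits are
    counted as unique track identities. Includes CLEAR-MOT tracking metrics
    (MOTA, MOTP, identity switches), counting metrics (ACP, MAE, RMSE), MOT-format
    text file input/output, and a seeded synthetic orchard-scene simulator for
    benchmarking the tracker without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
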