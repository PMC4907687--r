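Package: spacebytime
Title: Space-by-Time Decomposition of Single-Trial M/EEG Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes signed single-trial multichannel time series (such as
    epoched EEG) into trial-invariant non-negative temporal and spatial
    components combined by signed per-trial coefficients, using sample-based
    cluster non-negative matrix tri-factorization (scNM3F). Includes
    single-trial decoding of experimental conditions from the coefficients
    (Fisher LDA, leave-one-out cross-validation, ROC area, permutation
    significance tests), selection of the numbers of temporal and spatial
    components by stepwise decoding gain, cross-subject component clustering,
    a sliding-window LDA baseline, a synthetic-data generator emulating the
    assumed trial structure, and plain-text container I/O with a scriptable
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
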