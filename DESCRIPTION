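Package: adtgp
Title: Gaussian Process Correction of Droplet Noise in Antibody-Derived-Tag Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects droplet-specific technical noise in single-cell
    antibody-derived-tag (ADT) protein counts by Bayesian negative-binomial
    regression with a Gaussian-process per-cell offset learned from isotype
    control counts. Models raw counts directly with a log link; the
    exponentiated-quadratic kernel ties cells with similar isotype control
    counts so the posterior can be conditioned on equal technical noise
    across cells. Includes a masked-noise count simulator built on comonotone
    quantile coupling, a centered log-ratio (CLR) baseline with t-test
    differential expression, posterior fold-change and pseudo p-value
    summaries, and plain-text readers and writers for count and design
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
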