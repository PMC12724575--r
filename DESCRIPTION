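Package: velozone
Title: Data-Driven Velocity Thresholds for Athlete Movement Categories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives sport-specific movement-category velocity thresholds
    from 10 Hz athlete tracking velocity traces using a two-stage
    unsupervised procedure: velocity bins on a 0-10 m/s grid are linked by
    traversal (adjacent-sample transition) counts, smoothed with a
    beta-coefficient chain term, and partitioned by normalised spectral
    clustering; the number of categories is selected by the elbow method on
    the occupancy-weighted within-cluster sum of squares, and cohort
    thresholds are the per-match boundary means. Includes a semi-Markov
    locomotion simulator for synthetic match traces, GPS-style data
    cleaning (spike removal and file exclusion rules), zone distance
    quantification, and normality-gated two-sample cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
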