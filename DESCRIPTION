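Package: ehdscreen
Title: Cumulative Environmental Health Disparities Scoring for Census Tracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cumulative environmental health impact screening
    methodology for census tracts: per-indicator decile scores from rank-order
    of raw values, half-weighted aggregation of environmental-effects
    indicators into a Pollution Burden score, a Population Characteristics
    score from sensitive-population and socioeconomic indicators, and a final
    1-10 disparities rank from the product of the two. Includes the
    sensitivity analyses used to audit such tools (pairwise Spearman
    redundancy screening with moderate/high flags, principal component
    analysis on rank-transformed indicators), equity summaries (rank
    distributions by race and poverty deciles, high-impact tract flagging
    with driver indicators), a Gaussian-copula synthetic tract generator
    calibrated to a target Spearman correlation structure, and CSV/GeoJSON
    input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
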