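Package: buridan
Title: Locomotor Phenotyping of Walking Flies in Buridan's Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for centroid trajectories of flies walking in
    Buridan's paradigm (a round platform surrounded by water, with two
    opposing inaccessible vertical stripes). Computes twelve per-fly
    locomotor parameters (speed, distance, turning, meander, thigmotaxis,
    stripe deviation, walk counts and activity/pause structure), builds
    Gaussian-smoothed transition plots of moving-time occupancy, filters
    low-activity outliers, and groups sub-strains by principal component
    analysis with normality-gated two-way ANOVA and Tukey HSD post hoc
    contrasts. A correlated-random-walk simulator with two-state
    move/pause switching and von Mises stripe attraction generates
    synthetic studies so every stage of the pipeline is testable, including
    the uncorrelated random-walk baseline for stripe fixation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
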