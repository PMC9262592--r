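Package: rtvelocity
Title: Reverse-Transcriptase Velocity and Template-Obstacle Analysis from
    Primer-Extension Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and inference for reverse-transcriptase (RT)
    elongation kinetics on long RNA templates. Models primer extension as a
    constant-rate stepping process with structural obstacles, background
    dissociation, multiple-cycle rebinding and single-cycle trap conditions;
    renders simulated cDNA populations into the two standard readouts (denaturing
    gel lane densitometry with ladder calibration, and nanopore-style reads with
    SAM alignments); and implements the matching estimators: intensity-weighted
    mean cDNA length, read-length-distribution peak maxima, linear-regression
    velocity fits, the F_stop fraction of obstacle-terminated cDNAs, and
    per-position stop-site calling from alignment termini.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicAlignments,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
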