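Package: strainscan
Title: Strain Assignment and Introgression Scans for Two-Strain Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genomic inference pipeline for deciding whether an
    invasive insect population derives purely from one of two differentiated
    host-plant strains or carries introgressed ancestry from the other.
    Implements Weir-Cockerham F_ST in non-overlapping physical windows with a
    log-ratio scan and an individual-regrouping randomization null, Patterson's
    f3 three-population admixture test with block-jackknife standard errors,
    and genome-wide plus SNV-window ABBA-BABA D statistics, together with a
    structured-coalescent cohort simulator (two native strains, an invasive
    offshoot with an optional admixture pulse, and an outgroup) that writes
    VCF/popmap fixtures so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
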