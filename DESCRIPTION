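Package: truncamp
Title: Detection of Domain-Truncating Gene Amplifications from Segmented
    Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls gene-level amplifications from segmented somatic
    copy-number data (SEG format), classifies them as encompassing,
    overlapping or intragenic-breakpoint ("truncating") events relative to
    a single-transcript exon model, localizes the intragenic breakpoint,
    maps the minimal common region of amplification across a cohort, and
    quantifies the concordance of exon-block DNA copy number with
    exon-level RPKM expression via a 5'-block versus 3'-block log-ratio
    statistic tested with an exact Mann-Whitney U test. Ships a synthetic
    cohort generator with ground-truth labels for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
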