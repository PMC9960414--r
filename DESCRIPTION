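Package: metabosub
Title: Glycolytic/Cholesterogenic Metabolic Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies bulk RNA-seq tumor cohorts into four metabolic
    subtypes (quiescent, glycolytic, cholesterogenic, mixed) from the
    expression of glycolysis and cholesterol-biosynthesis pathway genes.
    Implements resampled consensus clustering of genes with CDF/delta-area
    diagnostics, core co-expressed cluster selection, quadrant subtype
    assignment on median pathway scores, Kaplan-Meier and log-rank survival
    comparison, somatic mutation and copy-number contingency analysis,
    immunoreactive score (IRS) computation, a pan-cancer screening loop,
    and a synthetic-cohort generator so the full pipeline is testable
    without controlled-access downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
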