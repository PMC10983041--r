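Package: svimpact
Title: Gene-Centric Integration of Structural Variant Breakpoints with
    Tumor Expression and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-centric association of structural variant (SV)
    breakpoints with tumor gene expression and patient survival. Harmonizes
    two-caller SV call sets with positional slop, computes breakpoint
    recurrence and descriptive SV statistics, builds gene-by-sample
    breakpoint matrices for genomic region windows (gene body, upstream and
    downstream flanks, 3' UTR, and a distance-weighted 1 Mb flank), fits
    covariate-corrected linear models of log expression on breakpoint
    pattern with Benjamini-Hochberg false discovery control, classifies
    enhancer-duplication and 3' UTR mechanisms, and derives signed survival
    gene signatures scored by a two-sample t statistic. Includes a synthetic
    cohort generator with planted cis-effects and hazards so the entire
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
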