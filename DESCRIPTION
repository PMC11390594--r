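Package: senotemp
Title: Temporal Meta-Analysis and Dynamic Modelling of Cellular Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for temporal meta-analysis of senescence transcriptomic
    comparisons and for simulating a protein-level model of DNA-damage- and
    oncogene-induced senescence. The meta-analysis half aggregates
    per-comparison log fold changes and p-values across studies with an
    inverted-p statistic, Tukey-fence outlier removal per gene and time bin,
    median significance calls, a four-inducer core-signature partition,
    rank tests for time-bin and inhibition contrasts, and a minimal
    preranked enrichment scorer; a seeded generator produces synthetic
    databases with planted effects for recovery scoring. The modelling half
    provides an event-driven ODE network of p53, p38, NF-kB and Notch
    signalling with senescence-induction, Notch-switch and knockdown
    events, a twelve-criterion phenotype checker, and dynamic scaled
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
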