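Package: secretomix
Title: Secretome Potency Profiling from Multiplex ELISA, EV-miRNA qPCR
    Arrays and Flow Cytometry Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mesenchymal stromal cell secretome potency from
    three assay layers. Multiplex ELISA panels are converted to per-cell
    secreted amounts with an all-samples detection rule, abundance tiers
    and inter-donor concordance summaries. EV-embedded miRNA qPCR-array
    Crt tables are spike-in equalized across panels, censored at the
    amplification limit, global-mean normalized to relative expression
    (2^-dCrt), reduced to the first quartile of expression, and scored
    for functional-category genetic weight. Primed-versus-resting
    contrasts use per-donor ratios with a one-sample t-test against 1,
    Grubbs outlier screening and a Lilliefors-style normality check.
    Flow-cytometry summaries yield background-subtracted MFI fold
    changes, CD86/CD163 polarization ratios and VCAM1-positivity ratios.
    A synthetic-data generator produces paired donor panels with known
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
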