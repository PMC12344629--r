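Package: n2okit
Title: Chamber N2O Flux Estimation, Isotopomer Source Attribution and
    Sulfate-Amendment Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for soil nitrous-oxide mitigation studies:
    static-chamber headspace flux estimation by linear regression and
    trapezoidal integration to cumulative emissions; agronomic metrics
    (water-filled pore space, yield-scaled emissions, percent reductions,
    treatment-by-year summary tables, net ion consumption); N2O isotopomer
    arithmetic (delta15N-alpha/beta, bulk, site preference), ambient-air
    mass-balance correction, end-member domain source classification and
    Monte-Carlo uncertainty propagation; one-way ANOVA with gatekept Fisher
    LSD and compact-letter display; unweighted response-ratio meta-analysis
    with one-sample t confidence intervals; and seedable synthetic-data
    generators so every stage is testable without field measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
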