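Package: resilind
Title: Resilience Indicators from Daily Step-Count Data for Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives resilience indicator traits from daily step-count time
    series of dairy cows and estimates their quantitative-genetic parameters.
    Record editing (partial-day rescaling, inclusion filters, gap trimming,
    estrus flagging), correction of step counts for herd-month and pregnancy
    status, per-lactation 0.7-quantile quartic lactation curves, and nine
    resilience indicators (stage means of corrected steps, log-variance,
    lag-1 autocorrelation, mean negative residuals, step-count drops).
    Includes a pedigreed herd simulator with known true genetic parameters,
    REML fitting of univariate and bivariate repeatability animal models
    using the additive relationship matrix, disease-association ANOVA, and
    partial genetic correlations adjusted for mean step count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
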