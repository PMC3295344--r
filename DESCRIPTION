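Package: prdmort
Title: Multicity Time-Series Analysis of Acute Oxidant Air Pollution and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for multicity time-series studies of acute air-pollution
    mortality effects of ambient oxidants (ozone, nitrogen dioxide) and
    particulate matter, modelled on four-city analyses in the Pearl River
    Delta. Implements hourly-to-daily exposure aggregation with completeness
    rules, quasi-Poisson regression by iteratively reweighted least squares
    with natural cubic spline smoothers for time trend and weather,
    PACF-guided degrees-of-freedom selection, excess-risk transformation,
    single- and two-pollutant models, peak/nonpeak stratified ozone analyses,
    sensitivity analyses, and Cochran's Q homogeneity testing across cities,
    together with a synthetic multicity data generator with known injected
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), splines, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
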