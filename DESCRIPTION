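Package: hrequity
Title: Equity Analysis of Regional Health-Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the fairness of health-resource allocation across the
    subregions of a larger territory from yearbook-style panel data. Implements
    the health-resource and population agglomeration degrees (resource or
    population share relative to land-area share) and their fairness ratio,
    objective indicator weighting by the entropy-weight method combined with
    TOPSIS composite scoring of regions, and economic-gradient concentration
    curves with the grouped trapezoid concentration index. Ships a synthetic
    yearbook-panel generator with controllable inequality structure (lognormal
    areas, populations and per-capita GDP; per-indicator economic-gradient
    exponents) so the whole pipeline can be exercised and verified without
    external data, plus an end-to-end pipeline runner and a thin command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
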