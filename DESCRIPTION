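Package: thermonet
Title: Quantile Transition Networks for Thermal-Imaging Fluctuation Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts thermal-imaging frame stacks (or any region-of-interest
    intensity series) into detrended, amplitude-normalized, pooled time series;
    maps them onto directed, unweighted transition networks over equiprobable
    quantile bins; and uses the cumulative distribution of edge betweenness
    centrality as a discriminator between healthy and pathological cohorts.
    Includes a seeded synthetic generator emulating ocular-surface cooling with
    autoregressive fluctuations and regime switching, a brute-force shortest-path
    oracle for validating edge betweenness, a cutoff classifier, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tiff,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
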