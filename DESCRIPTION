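Package: hdmea
Title: Spike Detection and Event Classification for High-Density Multielectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects extracellular spikes in raw voltage recordings from dense
    multielectrode arrays (thousands of electrodes on a square grid). Provides a
    streaming single-channel detector with incremental percentile baseline and
    noise tracking, a multi-electrode detector that interpolates signals onto
    virtual channels and localizes events at sub-electrode resolution, a
    ground-truthed synthetic benchmark with ROC analysis against a conventional
    band-pass threshold detector, and a rank-based correlation classifier that
    separates events participating in network activity from uncorrelated events
    using Poisson surrogates. Event tables are tibbles; results have broom-style
    tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
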