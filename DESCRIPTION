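Package: phidnet
Title: Gaussian Integrated Information Decomposition and Synergistic
    Workspace Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for information-theoretic analysis of multivariate
    neural timeseries under a Gaussian assumption. Implements the
    minimum-mutual-information partial information decomposition (MMI-PID)
    and its dynamical extension (integrated information decomposition) for
    pairs of regions: time-delayed mutual information, persistent synergy
    and redundancy, whole-minus-sum integrated information, and its
    revised non-negative form. Builds whole-brain synergy and redundancy
    networks, maps the synergy-redundancy rank gradient to identify
    synergistic workspace regions, classifies workspace regions into
    gateways and broadcasters via the participation coefficient, and tests
    condition contrasts with the network-based statistic and a composite
    least-favourable-configuration minimum-F permutation test for effects
    shared across datasets. Includes a first-order multivariate
    autoregressive generator with analytically controlled synergy and
    redundancy structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
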