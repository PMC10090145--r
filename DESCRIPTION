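Package: hyperchron
Title: Temporal-Topological Characterization of Higher-Order Evolving Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds higher-order evolving networks (temporal hypergraphs) from
    timestamped contact or hyperevent records and characterizes their
    temporal-topological structure: event-to-event topological distance on the
    pairwise aggregated graph, conditional distance-delay curves with slope
    statistics, order-targeted randomized null models, cross-order degree and
    strength relations, and egonetwork event-train analysis. Includes clique
    promotion of simultaneous pairwise contacts into group events, standard
    preprocessing (largest-component restriction, inactivity-gap removal,
    missing-link completion), seeded synthetic-network generators with
    plantable temporal-topological coupling, and tidy/ggplot2 output
    throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
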