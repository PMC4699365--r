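Package: screenminer
Title: Property-Graph Storage, Multi-Level Querying and Visual Analytics
    for High-Content Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Share and interactively mine image-derived feature data from
    high-throughput/high-content microscopy screens. Screens are imported
    from a typed three-header-row CSV dialect into a property graph of
    grouping objects (genes, strains, conditions), descriptive objects
    (cells) and metadata objects (images), with binary annotations
    attached from a label matrix. A multi-level query engine selects and
    aggregates numeric features at the grouping or descriptive level,
    filters by labels and numeric ranges at either level, applies axis
    transforms and rectangular area selections, and drills down from
    grouping-level selections to the underlying single-cell records. An
    analytics toolkit provides histograms and multi-histograms, Gaussian
    kernel density estimates, ordinary least-squares regression fits and
    plot comparison. Results export to CSV and SVG; complete query states
    serialize to URL-safe share tokens; a read-only JSON-over-HTTP service
    exposes the same query surface. A deterministic synthetic-screen
    generator with known ground truth makes every component testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    httpuv,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    callr,
    httr2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
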