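Package: annobench
Title: Continuous Benchmarking of Biomedical Annotation Servers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained harness for the continuous technical evaluation
    of biomedical named-entity annotation servers. Generates seeded synthetic
    document corpora emulating patent, abstract and PubMed-style providers
    with embedded ground-truth entity mentions; reads, writes, validates and
    interconverts three stand-off annotation interchange formats (BioC XML,
    BioC JSON, 8-column offset TSV); schedules regular and burst request
    loads against simulated or HTTP-reachable annotation servers; and derives
    reliability metrics (mean time between failures, mean time to repair) and
    performance metrics (average response time, annotations per document,
    time per document volume, time per annotation) from the resulting event
    logs, together with cache-compliance verdicts and leaderboard reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    curl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
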