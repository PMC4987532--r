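Package: coext
Title: Co-Extinction Robustness Analysis of Bipartite Host-Parasite Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates secondary (co-)extinctions in bipartite host-parasite
    networks. Hosts are removed one by one under best-case, worst-case,
    historical (vulnerability-ranked) and random scenarios; parasite richness
    is tracked after each removal and assemblage robustness is quantified as
    the area under the rescaled extinction curve. Includes a synthetic network
    generator in which parasites specialize on dependable (low-vulnerability)
    hosts, structure metrics (NODF nestedness, Barber bipartite modularity,
    C-score) with curveball fixed-degree null models, vulnerability-richness
    correlation analyses, and sensitivity experiments for incomplete
    interaction data and tied vulnerability rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
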