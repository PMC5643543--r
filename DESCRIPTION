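Package: trionet
Title: Trio Motif Census and Disease Comparison for Microbiome Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed OTU co-occurrence networks from abundance tables
    (Spearman or Pearson correlation with Benjamini-Hochberg false discovery
    rate control), enumerates and classifies every triangle motif ("trio")
    under a three-level, 19-type scheme anchored on a focal node (by default
    the most abundant OTU, MAO), and compares diseased against healthy
    networks with the ratio of disease to healthy trios (RDHT), including a
    balanced-resampling protocol for unequal group sizes. Ships a synthetic
    data generator (Gaussian-copula negative-binomial counts with planted
    correlation blocks, and random signed graphs with planted motifs) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
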