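Package: planktonnet
Title: Correlation Networks of Microbial Food Webs from Plankton Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses co-occurrence networks of microbial food web
    components (viruses, bacteria, phytoplankton, heterotrophic flagellates,
    naked ciliates and tintinnids) from weekly plankton abundance time series.
    Segments chlorophyll-a fluorescence into bloom and non-bloom periods from
    daily net growth rates, infers signed Spearman correlation networks with
    Monte-Carlo permutation p-values, summarises them with descriptor tables
    and hubs, classifies between-group edge counts as rare or dominant against
    Erdos-Renyi G(n,m) null models, derives organism size classes from
    equivalent spherical diameters with a PELT changepoint segmentation,
    selects biomass-dominant taxa from spherical biovolumes, and compares
    years by ISO-week paired Wilcoxon signed-rank tests. Includes a synthetic
    plankton community generator with planted correlation structure and bloom
    windows so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
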