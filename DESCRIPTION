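Package: scimint
Title: Multivariate Syndromic Analysis of Pooled Preclinical Injury Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening pooled preclinical trials for multivariate
    therapeutic effects. Implements Mapper-style topological data analysis
    with bootstrap consensus over subjects, syndromic principal component
    analysis of heterogeneous outcome batteries with Kaiser/scree/
    over-determination retention and orthogonal polynomial dose-response
    contrasts, a four-step gene co-expression module procedure (biweight
    midcorrelation, complete-linkage clustering with a top-quantile cut,
    eigengene summarization, iterative eigengene merging, kME), and
    differential-expression reversal classification with hypergeometric
    gene-set over-representation. Includes seeded generators for a multi-arm
    outcome table and a planted-module count matrix so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
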