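Package: wisecell
Title: Weighted and Integrated Gene Set Enrichment for Cell-Type Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates scRNA-seq cell clusters from ranked lists of
    differentially upregulated genes using a weighted and integrated gene
    set enrichment statistic: a frequency-weighted hypergeometric
    over-representation test against canonical cell-type markers is combined
    by Fisher's method with a positive-side pre-ranked GSEA against
    rank-aggregated differential-expression gene lists, then
    Benjamini-Hochberg adjusted across candidate cell types. Includes the
    marker-map data model (tissue-specific cell-type hierarchies,
    usage-frequency tables, robust-rank-aggregated DEG lists, pan-tissue
    merging), hierarchy-aware accuracy scoring of annotations, clustering
    diagnostics across resolutions, a seeded synthetic fixture generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
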