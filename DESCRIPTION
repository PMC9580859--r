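Package: metaexpress
Title: Integrating Metagenomes and Metatranscriptomes into Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational building blocks for integrated metagenome and
    metatranscriptome analysis of microbial communities: read-length cutoff
    estimation and adapter-index detection for quality control, scoring and
    dereplication of metagenome-assembled genomes (MAGs), TPM and single-copy
    marker-gene normalization of per-gene read counts, integration of DNA and
    RNA abundance profiles into gene-expression profiles that separate
    per-gene expression change from community turnover, aggregation of gene
    profiles into functional (KEGG/eggNOG/Pfam/dbCAN) profiles with overlap
    summaries, and Bray-Curtis/PCoA community ordination. A synthetic fixture
    generator with known ground truth makes every stage testable at desk
    scale without external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vegan,
    jsonlite
Config/testthat/edition: 3
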