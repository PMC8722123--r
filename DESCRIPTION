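Package: acetylseq
Title: Genome-Wide Analysis of DNA Cytosine N4-Acetylation IP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of N4-acetyldeoxycytosine (4acC) IP-seq
    together with companion epigenomic tracks: IP-versus-input enrichment
    peak calling with replicate consensus, genomic feature annotation with
    observed-versus-expected enrichment tests, metagene and chromosome-scale
    profiles, bisulfite methylation statistics in the CG/CHG/CHH contexts,
    differentially acetylated and methylated region calling, interval
    colocalization enrichment against length-matched random-region nulls,
    and combinatorial mark-by-expression statistics. Includes a coupled
    synthetic-epigenome generator with a ground-truth manifest so every
    stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
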