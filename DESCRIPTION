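Package: recsplice
Title: Detection, Filtering and Differential Quantification of Recursive Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate recursive splice sites (RSSs) from hybrid
    splice-junction evidence at intronic YAG|NN motifs, applies the
    three-criterion filter used for total RNA-seq data (per-motif
    conservation, junction overhang support, and a sawtooth intronic
    coverage pattern assessed by a breakpoint permutation test) together
    with poly(A)-library subtraction, quantifies per-sample RS usage from
    junction reads, tests differential usage between genotypes, and
    computes downstream annotation statistics (RS-exon association,
    cryptic-exon coverage enrichment, donor-dinucleotide enrichment,
    conservation stratification and profiles, RSS-per-million and
    intron-length correlation, alternative-splicing overlap enrichment).
    Ships a ground-truthed synthetic data generator emitting the standard
    input formats (FASTA, GFF3, bedGraph, STAR-style junction tables) so
    the whole pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
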