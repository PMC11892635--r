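Package: bicistroscan
Title: Sequence Analysis of Bicistronic Loci in Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and characterisation of exclusively bicistronic
    transcripts from genome FASTA and GFF3 annotations. Builds Kozak-like
    consensus position weight matrices from monocistronic genes, scores
    initiation-site contexts as information-content bit scores, computes
    ORF1:ORF2 score ratios, GC-adjusted AUG 3-mer observed/expected
    depletion statistics, colinearity-based conservation calls from
    tabular homology hits, and ORF-level RNA-Seq/Ribo-Seq correlation
    summaries. Includes an auditor for synthetic bicistronic construct
    design under the leaky ribosomal scanning model, and a synthetic
    genome/expression/homology generator with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
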