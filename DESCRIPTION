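Package: consmut
Title: Consensus-Mutagenesis Construct Design from Protein Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs thermostabilized variants of a target protein by consensus
    mutagenesis. Every position of a wild-type reference is scored by the ratio
    f(cons)/f(WT) of the most frequent amino acid's column frequency in a
    homolog multiple sequence alignment to the wild-type residue's frequency;
    substitutions whose ratio exceeds a threshold, optionally restricted to a
    region mask such as transmembrane segments, are combined into mutant
    constructs. Threshold sweeps produce graded panels of constructs labelled
    by mutation load, together with score tables, mutation tables, annotated
    alignments and panel summaries. A synthetic-alignment generator with
    exactly specified per-column residue distributions provides computable
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Proteomics, StructuralPrediction
RoxygenNote: 7.3.3
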