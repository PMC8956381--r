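Package: haplogrouper
Title: Haplogroup Classification and Tracking for Fragmented Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies human mitochondrial DNA haplogroups from fragmented
    sequence data such as ancient DNA amplicons. Sample fragments are aligned
    to the rCRS coordinate system with an affine-gap global aligner, variants
    are called in Phylotree notation, and candidate haplogroups are ranked by
    a fragment-range-aware variant identity together with a private-variant
    frequency score derived from a haplotype database built by iterative
    self-classification of a sequence corpus. An iterative tracking loop
    proposes discriminating amplicons to narrow multi-candidate calls down to
    a single haplogroup, and an in-silico simulator measures the minimum
    number of amplicons needed to type each haplogroup. Includes synthetic
    generators for toy haplogroup trees, sequence corpora and damaged
    ancient-DNA-style fragments used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
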