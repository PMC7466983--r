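Package: evoprintr
Title: Phylogenetic Footprinting with EvoPrints, Conserved Sequence Blocks
    and Cross-Taxon uCSB Mapping
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects multi-species sequence conservation onto a reference
    at near base-pair resolution. A BLAT-style k-mer seeded local aligner
    (seed lengths 9 and 11, ungapped x-drop extension, colinear chaining)
    aligns each test species to the reference; per-species match calls are
    combined into strict and relaxed EvoPrints (uppercase = conserved,
    lowercase = diverged), from which maximal conserved sequence blocks
    (CSBs) and CSB clusters are called. Reference CSBs can be mapped into
    distantly related taxa to identify ultraconserved CSBs (uCSBs), with
    linear-order (colinearity) and orientation (microinversion) analysis
    and two-target sharing classification. A sequence-evolution simulator
    with known ground truth (conserved blocks in rapidly diverging
    spacers, star phylogeny, spacer indels, optional block inversions and
    translocations) supports end-to-end testing, and a small CLI wires the
    steps into composable commands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
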