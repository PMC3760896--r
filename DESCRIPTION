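Package: nifcore
Title: Conservation-Core Analysis of Nitrogenase Component 1 Sequence Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reference-anchored analysis of multiple sequence alignments of
    the nitrogenase Component 1 alpha- and beta-subunits (NifD/K, AnfD/K,
    VnfD/K). Anchors alignment columns to a reference residue numbering
    across insertions and deletions, delimits the co-aligned core, classifies
    each core column into conservation classes (invariant, three single
    variant subtypes, double variant, dominant, variable), computes
    between-group co-invariance matrices and group-exclusive strong motifs,
    assigns new sequences to groups by their motif ensemble and indel
    fingerprint, overlays conservation classes onto 5 Angstrom contact shells
    around metal clusters in atomic coordinates, and scans coding sequences
    for selenocysteine amber-codon read-through. Includes a synthetic family
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
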