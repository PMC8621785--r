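Package: lassotopo
Title: Detection and Classification of Complex Lasso Motifs in Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and annotates complex lasso motifs in protein
    (or generic polymer) three-dimensional structures. A covalent loop -- a
    backbone segment closed by a disulfide, amide, ester, thioester or C-C
    side-chain bridge -- is spanned by an approximately minimal triangulated
    surface, and oriented crossings of the terminal tails through that surface
    are detected, reduced to genuine piercings and turned into the lasso
    nomenclature (L, LS, LL, LLS minor and major types) and the per-chain lasso
    fingerprint. Additional modules score the stabilization of piercing
    residues from bulky-residue concentration and B-factor (or NMR
    ensemble mean-square-deviation) profiles, classify bridge conservation
    from precomputed multiple sequence alignments, aggregate survey
    statistics, and deterministically generate synthetic chains with
    prescribed lasso types for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
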