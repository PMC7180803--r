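Package: idrlib
Title: Mining Disordered Sequence Patterns from Clustered Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a library of intrinsically disordered sequence patterns from
    a clustered set of x-ray protein structures. Annotates per-residue disorder
    from missing electron density (REMARK 465 / SEQRES vs ATOM records),
    clusters chains into a nested hierarchy at 100/75/50/25/5 percent sequence
    identity, computes two-level cluster-weighted disorder statistics, detects
    low-complexity AC2 segments (exactly two amino-acid types) and homo-repeats
    with closed-form null occurrence probabilities, synthesises wildcard
    (X-masked) candidate patterns from near-identical homologues, and selects a
    non-redundant pattern library by an iterative greedy procedure scored by the
    excess of disordered over ordered matched residues. Includes a synthetic
    fixture generator (toy PDB entries, mutated chain families, planted motifs)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
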