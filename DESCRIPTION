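Package: fraglib
Title: Fragment Libraries from Compound Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and characterizes terminal-fragment libraries from
    compound collections such as natural-product and screening databases.
    Provides a light-weight molecular graph with SMILES input/output and
    canonicalization, a standardization/curation pipeline (normalization,
    largest-fragment selection, neutralization, canonical tautomer,
    stereochemistry removal, element and molecular-weight filters),
    RECAP retrosynthetic fragmentation restricted to terminal fragments,
    structural descriptor profiling, fingerprint-based diversity statistics
    (median pairwise Tanimoto similarity with random-sample averaging),
    cross-library overlap reports, and MinHash/LSH-forest approximate
    nearest-neighbor graphs with spanning-tree layouts for chemical-space
    mapping. Includes a seeded synthetic-data generator that assembles
    molecules from fragmentation-inert building blocks with known expected
    terminal fragments, so every stage can be validated without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
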