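Package: stabdesign
Title: Conservation-Guided Computational Design of Thermostable Enzyme Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for computational enzyme stabilization:
    scan a homolog alignment for conservation-favoured point mutations via a
    position-specific scoring matrix (PSSM), attach predicted folding
    free-energy changes (ddG) from a built-in surrogate scorer or an external
    per-mutation table, filter candidates through a battery of deterministic
    structural exclusion rules (active-site proximity, unsatisfied hydrogen
    bonds, exposed hydrophobics, loop flexibility, proline-in-helix, cavity
    creation), combinatorially design multi-mutant variants by Monte-Carlo
    rotamer packing plus perturb-minimize relaxation, and select final
    designs by C-alpha RMSD and total-energy decrease relative to wild type.
    Includes a synthetic-fixture generator (ideal helices, planted-signal
    alignments, SASA cages, enumerable packing instances) so the whole
    protocol can be exercised and validated without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
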