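Package: cgbeta
Title: Beta-Structure, Surface and Self-Assembly Analysis for Coarse-Grained Peptide Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained (one-bead-per-residue) and
    C-alpha-reduced peptide and protein models. Assigns beta-sheet structure
    from backbone-bead geometry alone (extended pseudo-dihedrals plus
    inter-strand bead contacts), computes Shrake-Rupley solvent-accessible
    surface areas and buried interface areas between molecular groups,
    characterizes peptide aggregates and detergent micelles by single-linkage
    clustering, and checks amphipathic beta-peptide design rules (alternating
    hydrophobic/hydrophilic pattern, length, terminal charge complementarity).
    Ships deterministic synthetic-geometry generators (extended strands,
    beta sheets and barrels, self-avoiding coils, helical-bundle membrane
    protein mimics with detergent shells) so every analysis is testable
    without molecular dynamics output, plus readers and writers for GRO and
    (multi-model) PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
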