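Package: tcrlens
Title: Comparative Structural and Energetic Analysis of TCR-pHLA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing wild-type and affinity-enhanced T cell
    receptor (TCR) complexes with peptide-HLA (pHLA) antigens. Computes
    binding-geometry metrics (crossing angle, docking footprint over the
    peptide-binding groove, per-loop backbone displacement), enumerates and
    classifies interface contacts (van der Waals, hydrogen bond, salt
    bridge), measures solvent-accessible surface burial and Lawrence-Colman
    shape complementarity, compares per-residue flexibility (RMSF) across
    replica coordinate ensembles with significance testing, and estimates
    relative binding energies with a simplified single-trajectory MM/GBSA
    scheme including per-residue decomposition and favourable/unfavourable
    classification. Ships seeded generators of toy complexes, replica
    ensembles and parameter sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
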