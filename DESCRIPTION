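Package: peptscan
Title: Transient Binding-Site Detection for Unstructured Peptide Fragments
    on Receptor Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating transient binding sites of intrinsically
    disordered peptide fragments on a folded receptor from molecular
    dynamics trajectories. Implements the RASAS occupancy measure (the
    ratio of a binding site's solvent-accessible surface area in the
    presence of a ligand to its value with the ligand ignored), a
    whole-surface coverage metric, switched-cutoff Coulomb and
    Lennard-Jones interaction-energy series, salt-bridge detection, and a
    multi-criterion site-calling pipeline (centroid contact pairing,
    per-residue energy screening, fragment splitting, spatial merging and
    re-scoring). Includes an overlapping-fragment segmenter for
    unstructured tails, alignment-column conservation classification, a
    synthetic trajectory generator with planted ground-truth binding
    events, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
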