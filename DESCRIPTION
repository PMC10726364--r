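Package: ringalign
Title: Intramolecular Aromatic Ring Alignment and Switching Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometric descriptors of intramolecular aromatic side-chain
    organization in minimal peptoids and peptides: the ipso/para distance
    ratio rho, the para-ipso-ipso-para inter-ring torsion lambda, frame-to-
    frame delta-lambda switching statistics with bootstrap uncertainty, the
    cross-amide-state homogeneity parameter eta, and rho-lambda occupancy
    surfaces. Includes multi-model PDB and XYZ trajectory ensemble I/O, a
    synthetic trajectory generator with exact descriptor-level ground truth
    for validation without a molecular dynamics engine, and an exhaustive
    grid-search partial-charge fitting protocol scored against water-probe
    interaction energies with dipole-overestimation filtering.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
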