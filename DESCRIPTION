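Package: motioncons
Title: Motion-Conservation Analysis of Paired Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for comparing a chemically modified
    biomolecular complex against a wild-type reference: Kabsch-superposition
    RMSD series, pairwise Coulomb/van der Waals interaction-energy
    decomposition between atom groups, geometric hydrogen-bond census,
    contact-residue shells, active-site distance tracking, and a
    motion-conservation statistic built on essential-dynamics PCA of the
    C-alpha covariance matrix: directional similarity (sigma_mn) between
    principal modes of two systems, its diagonal/off-diagonal sums
    (Sigma_C, Sigma_U) classifying the leading motions as conserved or
    swapped, and a per-residue decomposition of Sigma_C. Includes a
    synthetic-ensemble generator with planted principal modes that supplies
    ground-truth test beds for every analysis, and a config-driven pipeline
    that reproduces the full multi-system comparison workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
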