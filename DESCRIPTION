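Package: memallo
Title: Membrane Allostery Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for locating state-dependent lipid
    interaction sites on membrane proteins such as pentameric ligand-gated
    ion channels. Implements perturbation response scanning (linear-response
    prediction of per-residue displacements under point forces, scored by
    overlap with a target conformational change), time-averaged 3D lipid
    occupancy grids with an occupancy-fraction reporting filter, dual-cutoff
    lipid-residue contact detection with survival-curve residence-time
    estimation and residue-graph binding-site clustering, and atomistic
    interaction fingerprints (hydrogen-bond and hydrophobic classes),
    atom-pair distance series, RMSD series and a simple pore-radius profile.
    A synthetic-data module generates Gaussian fluctuation ensembles with
    known covariance, coarse-grained lipid random walks with planted binding
    kinetics, and hydrogen-bond geometry fixtures, so every stage is testable
    against planted truth without microsecond simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
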