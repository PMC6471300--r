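Package: tunnelscape
Title: Collective-Variable Design and Well-Tempered Metadynamics for
    Ligand Diffusion in Protein Tunnel Cavities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing ligand motion inside tunnel-like
    protein cavities, such as the hydrophobic channel of plant lipid
    transfer proteins. Derives a diffusion axis from pocket-occupancy
    volumetric grids (OpenDX) by covariance eigendecomposition, defines
    two collective variables (axial and radial ligand displacement) in an
    optimally fitted roto-translational reference frame selected by
    per-atom fluctuation (RMSF), runs well-tempered metadynamics with
    harmonic confining walls on analytic model potentials via an
    overdamped Langevin integrator, reconstructs and analyzes the
    resulting free-energy profile (basins, barriers, convergence of
    energy deposition), and performs auxiliary analyses: logistic
    contact-covariance residue clustering, PCA-histogram configurational
    entropy, Gibbs free-energy assembly from enthalpy and entropy terms,
    and cavity-volume/collective-variable correlation. Includes
    synthetic-data generators (toy potentials with analytic free-energy
    profiles, scaffold-plus-ligand trajectories with known collective
    variable ground truth, pocket grids with a known principal axis) and
    a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
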