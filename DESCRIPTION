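Package: flipsampler
Title: Enhanced-Sampling Toolkit for Two-State Conformational Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale enhanced-sampling pipeline for mapping two-state
    conformational equilibria such as the stacked-in/bulged-out base flip of
    an RNA hairpin. Provides an analytic two-basin model with a hidden
    hydration-like coordinate and a tunable ligand-stabilization term, a
    counter-seeded BAOAB Langevin integrator, harmonic linear discriminant
    analysis (HLDA) collective variables, OPES-Explore kernel bias layers with
    a hard barrier cap, a multithermal expanded-ensemble ramp, an
    8-replica OneOPES-style exchange ladder, free-energy-surface reweighting
    with basin free-energy differences and convergence diagnostics, and
    trajectory analytics (Kabsch superposition, RMSD/RMSF, gromos clustering,
    dynamic cross-correlation maps, interface contact frequencies, principal
    motion modes). Readers and writers for PDB, XYZ, COLVAR-style tables and
    PLUMED-syntax collective-variable export are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp (>= 1.0.0), stats, utils, yaml, bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
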