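Package: pullMD
Title: Coarse-Grained Pulling Simulations and Unbending Mechanics of Bent
    Multidomain Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying force-induced unbending of bent multidomain
    adhesion receptors at coarse-grained resolution. Provides a bead-spring
    builder for a bent two-chain ectodomain with breakable headpiece-tailpiece
    contacts and two knee hinges, an overdamped Langevin engine implementing
    free, constant-velocity and constant-force pulling protocols, and the
    trajectory analyses used in steered molecular dynamics studies of
    integrin-like molecules: Shrake-Rupley solvent-accessible surface area
    and buried interface area, geometric hydrogen-bond detection, Hingefind
    style inter-domain hinge angles with cooperativity fits, extension and
    centre-of-mass distance series, force-peak detection, waiting-time
    extraction and Bell-model force-dependent kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
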