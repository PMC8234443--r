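Package: stenoflow
Title: Finite-Difference Simulation of Pulsatile Casson Hybrid-Nanofluid
    Flow in Constricted Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vorticity-stream-function finite-difference solver for
    two-dimensional pulsatile flow of a Casson (yield-stress) hybrid
    nanofluid through a channel with symmetric cosine-shaped wall
    constrictions, a model problem for blood flow in stenosed arteries.
    Includes magnetic (Hartmann) drag, Darcy porous drag, Rosseland
    thermal radiation and Soret-coupled solute transport. The constricted
    domain is mapped to a rectangle, the stream-function Poisson equation
    is solved by tridiagonal (Thomas algorithm) line relaxation, and the
    vorticity, temperature and concentration transport equations are
    advanced with an alternating-direction-implicit scheme. Provides
    two-step Maxwell mixture models for the effective thermophysical
    properties of mono and hybrid nanofluids, wall shear stress,
    skin-friction, Nusselt and Sherwood diagnostics, one-factor parameter
    sweeps with monotone-trend reports, and a verification harness
    (manufactured solutions, analytic plane-channel limits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
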