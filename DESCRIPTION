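Package: ecoepi
Title: Nonautonomous Diffusive Eco-Epidemic Predator-Prey Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a seasonally forced eco-epidemiological
    model in which an infectious disease splits the prey population into
    susceptible and infected compartments and a predator consumes infected
    prey through a Beddington-DeAngelis functional response.  The package
    represents time-periodic coefficients, reduces the reaction-diffusion
    system to its spatially homogeneous ordinary differential equations,
    computes ultimate persistence bounds and the hypothesis margins that
    certify permanence and global stability, locates the positive periodic
    orbit as a fixed point of the Poincare map, and simulates the full
    one-dimensional reaction-diffusion system with zero-flux boundaries,
    together with diagnostics (Lyapunov decay, envelope bracketing by
    ordinary-differential-equation solutions, persistence-band entry times,
    oscillation-period estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
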