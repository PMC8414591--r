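Package: musasi
Title: Stochastic Cross-Bridge Half-Sarcomere Model with Implicit Active
    Stiffness Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of the myosin cross-bridge cycle in a
    half-sarcomere (six molecular states, troponin/tropomyosin calcium gating
    with nearest-neighbour cooperativity, strain-dependent power and reverse
    stroke kinetics under detailed balance) coupled to implicit continuum
    mechanics by a multiple-time-step scheme: many microsecond Monte Carlo
    steps per millisecond macro step, with active tension and a consistent
    active stiffness re-evaluated from the trial end-of-step stretch inside
    Newmark-beta Newton iterations.  Includes destination-strain-energy and
    barrier-strain-energy power-stroke rate laws, uniaxial and serial
    myofibril-chain mechanical testbeds, and physiological protocols
    (force-pCa, force-velocity, twitch, spontaneous oscillatory contraction,
    explicit/implicit stability sweeps).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
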