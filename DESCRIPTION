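Package: osseowave
Title: Poroelastic Discrete-Element Simulation of Dental-Implant
    Osseointegration Under Shock-Wave Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A movable-cellular-automaton-style poroelastic discrete-element
    simulator of a layered mandibular bone/implant system driven by
    extracorporeal shock-wave (ESWT) pulse trains or physiological occlusal
    loading. Builds FCC particle packings of a gingiva/cortical/cancellous
    block with a cylindrical titanium implant inside a peri-implant healing
    shell whose material follows the osseointegration phase, couples an
    explicit Newton-Euler pair-mechanics core to Biot pore-fluid pressure,
    and classifies the resulting per-element mean stress, shear strain and
    pore pressure fields into tissue-differentiation fates by published
    mechanobiological thresholds, reported as peri-implant volume fractions.
    Includes analytic verification drivers (Terzaghi consolidation, modulus
    recovery, wave speed, stiffness convergence) and VTK/CSV field output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
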