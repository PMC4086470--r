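Package: ossidrive
Title: Coupled Piezoelectric-Stack and Middle-Ear Models for Implantable
    Hearing Actuators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale computational model of an incus-body driving
    piezoelectric middle ear implant. Implements a fully coupled
    electromechanical finite element model of a multilayer PZT-4 stack
    actuator (hexahedral elements, symmetric block assembly of the
    mechanical, piezoelectric-coupling and dielectric matrices), a
    lumped-parameter surrogate of the human ossicular chain, an axial
    coupling-rod model, and harmonic-response solvers. Evaluation metrics
    include the stapes velocity transfer function, equivalent sound
    pressure level, coupling-rod insertion penalty in decibels, and
    actuator capacitance, current and power consumption.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
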