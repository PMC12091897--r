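Package: prfield
Title: Pinsky-Rinzel Two-Compartment Neuron Under DC Induced Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Pinsky-Rinzel two-compartment CA3 pyramidal neuron
    model under a constant (DC) induced electric field, using the classical
    fixed-step fourth-order Runge-Kutta scheme. Provides spike detection,
    mean-firing-rate computation and an eleven-state firing-regime classifier,
    together with one- and two-dimensional parameter sweeps over field
    amplitude, injected current, coupling conductance and potassium reversal
    potential, from which the field-sensitivity interval of the neuron is
    measured. Includes CSV/JSON input-output, a flat-file configuration
    reader, synthetic fixture traces for every regime label, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
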