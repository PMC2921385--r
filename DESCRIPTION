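Package: rootauxin
Title: Self-Organising Auxin Patterning Along the Root Axis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and hybrid stochastic models of polar auxin
    transport along the central axis of a plant root. Implements the
    reflected-flow mechanism, in which auxin activates expression of its
    PIN1 efflux carrier at low concentration and promotes PIN1 degradation
    at high concentration, so that a distal auxin maximum self-organises a
    few cells from the root end. Provides a 1D cell-file model and a 2D
    provascular/epidermal layout solved with stiff (BDF) integration and
    Newton steady states, a hybrid deterministic-stochastic model of a
    growing, dividing cell file with a Division Factor morphogen,
    pseudo-arclength parameter continuation with fold detection and
    stability analysis, oscillation and maxima detection, perturbation
    tolerance measurement, profile comparison against digitized reporter
    data, and coordinatewise-descent parameter fitting, together with
    scripted in-silico experiments (flux ramps, transport-inhibitor
    treatment, tip ablation, exogenous auxin).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
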