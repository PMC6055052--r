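Package: rschd
Title: Retrosplenial Bidirectional-Cell Network Model of Head-Direction Landmark Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate network model of how retrosplenial cortex couples an
    anterodorsal-thalamic head-direction (HD) ring signal to environment-driven
    visual inputs. Hebbian self-organisation of the HD-to-bidirectional-layer
    synapses produces within-compartment (conjunctive) and between-compartment
    (environment) bidirectional cells in rotationally symmetric multicompartment
    apparatuses, degrades tuning specificity under four-fold symmetry, and lets
    distal but not proximal landmarks stabilise a noisy path-integrated HD
    signal. Includes apparatus builders, random-walk trajectory generation, a
    leaky-integrator rate network with a ring-attractor HD stage, the full
    tuning-curve analysis pipeline (6-degree binning, preferred firing
    directions, rotational autocorrelation, peak counting, drift reports), and
    scripted end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
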