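Package: thermoflow
Title: Digital Twin of a Multilayer Thermal-Gradient Blood Flow Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inverse modelling of a skin-interfaced
    calorimetric blood-flow sensor. Provides a three-dimensional
    finite-volume solver for steady and transient conduction plus
    advection-diffusion heat transport in a phantom/vessel/actuator
    system, a thermistor and Wheatstone-bridge signal-chain model,
    generators for synthetic benchtop datasets with condition-grouped
    cross-validation splits, a multilayer-perceptron regressor that
    simultaneously recovers flow rate and vessel depth from six thermal
    channels, and a two-branch flow+photoplethysmography fusion model for
    continuous blood-pressure estimation with Bland-Altman agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
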