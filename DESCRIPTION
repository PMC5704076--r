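Package: sticksearch
Title: Neuromuscular Model of Stick-Insect Front-Leg Search Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a reduced one-leg neuromuscular model of searching
    movements of the stick-insect front leg: two half-centre central pattern
    generators driving the levator-depressor and extensor-flexor muscle
    systems through premotor interneurons and fast/slow motoneuron pools,
    coupled by threshold-gated sensory conductances on the joint angles.
    Implements the obstacle perturbation/recovery protocol (motoneuron
    silencing with passive rigidity hold, staged reactivation, obstacle
    position dependent recruitment slow-down) and the analysis layer used to
    characterise recovery: beta-gamma state diagrams with triangular versus
    quadrilateral loop classification, oscillation-cessation and
    alternating-amplitude detection, and oscillation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
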