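Package: mirdesign
Title: Globally Optimal Design of miRNA-Based Boolean Cell-Classifier Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design tools for synthetic cell-classifier circuits that sense
    binarized microRNA (miRNA) expression profiles and decide whether a cell is
    diseased.  A classifier is a Boolean function in conjunctive normal form
    whose clauses ("gates") must respect laboratory-feasibility constraints:
    bounds on the number of gates, total inputs, per-gate-type input signs and
    gate-type occurrences.  The package reads binarized (and continuous)
    expression tables, performs a complete, globally optimal search for
    feasible classifiers under four input/gate minimization hierarchies,
    enumerates all optima up to gate-relabeling isomorphism, relaxes false
    negative/false positive error bounds stepwise when no perfect classifier
    exists, scores classifiers in Boolean (error rates) and continuous
    (AUC and output-margin) settings, and provides synthetic benchmark
    generators with conservative k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
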