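Package: mfgsim
Title: Functional-Group Dynamics of the Colonic Microbiota in Continuous Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of a human colonic microbial community in
    pH-controlled continuous culture. Ten microbial functional groups (M1-M10)
    are represented by stochastic strain ensembles growing by Monod kinetics
    under trapezoidal pH response curves and selective noncompetitive lactate
    inhibition, coupled to explicit fermentation stoichiometries for
    short-chain fatty acids, lactate, formate and gases. Includes scenario
    runners for lactate infusion, pH and lactate-utilizer abundance
    experiments, a taxon-to-functional-group inoculum mapper, and tools to
    explore community collapse at mildly acidic pH.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
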