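Package: tracerMID
Title: Isotopologue Analysis of 13C Tracer GC-MS Experiments in
    Naphthalene-Degrading Anaerobes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative stable-isotope tracing of carbon
    metabolism in slow-growing anaerobic cultures. Implements the
    three-step linear-regression correction that converts GC-MS
    selected-ion-monitoring intensities of TBDMS amino acid and fatty
    acid methyl ester fragments into 13C excess values (removing
    derivatization-reagent isotopes and natural abundance by
    non-negative least squares), binomial labeling models and
    carbon-pool mass balances for culture bottles, scenario-based
    prediction of mass isotopomer distributions under competing
    acetyl-CoA provenance hypotheses (direct assimilation from the
    aromatic substrate, chemoorganoautotrophic CO2 fixation, carboxyl
    exchange), inference of the autotrophic fraction of anabolic
    acetyl-CoA, a seeded synthetic-data generator with realistic
    technical and biological noise, and reduction of spectrophotometric
    enzyme assay traces to specific activities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
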