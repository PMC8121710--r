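Package: nucleoflip
Title: Syn/Anti Glycosidic Dynamics and Interface Fingerprints for
    Protein-RNA Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for molecular-dynamics trajectories of
    protein-RNA complexes, centred on the distal-side binding of
    ARN-repeat RNA by the bacterial chaperone Hfq. Computes glycosidic
    chi torsions, classifies nucleotides as syn or anti, debounces
    short-lived excursions before counting transitions, and summarises
    dwell statistics (transition counts, state populations, times to
    first transition, mean lifetimes). Detects per-frame geometric
    interactions at the interface: hydrogen bonds, water and ion
    bridges, guanine-specific type-4 base-phosphate (4BPh) contacts and
    van der Waals contacts, with occupancy aggregation and
    state-conditioned distance histograms. Includes coordinate-
    covariance principal component analysis, evaluation of the HBfix
    flat-ramp hydrogen-bond bias potential, and a ground-truth-labelled
    synthetic trajectory generator so every stage is testable without
    microsecond-scale raw trajectories.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
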