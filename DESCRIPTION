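Package: ivscreen
Title: Inverse Virtual Screening with Decoy-Normalized Docking Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Target identification by inverse virtual screening: one or a
    few query compounds are docked against a large panel of protein
    structures and putative targets are ranked by the dimensionless ratio
    V = V0/VR of the query's best-pose binding affinity to the mean
    affinity of a property-matched decoy set against the same structure.
    Provides property-matched decoy selection (molecular weight, hydrogen
    bond donors/acceptors, fingerprint dissimilarity), docking-box
    construction from binding-site definitions, parsing of docking-engine
    score output, threshold filtering and non-redundant target ranking
    with occurrence statistics, multi-compound target intersection, and
    post-hoc molecular dynamics analytics (per-residue interaction
    occupancy fractions and superposed protein RMSD traces). A synthetic
    campaign and trajectory generator makes every stage testable without
    external docking or simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
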