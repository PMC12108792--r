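Package: nucdamage
Title: Damage Constructs and Recognition Geometry for Nucleosomal DNA
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to build uracil, flipped-base and single-strand-break (SSB)
    constructs at defined superhelical locations (SHL) of a nucleosome, and to
    quantify recognition-relevant geometry on conformational ensembles: SSB gap
    distance (dg), local twist dihedral (Phi), inter-gyre gaping (dw), probe
    and hydrogen-bond distances, RMSD, GROMOS neighbor-counting clustering, and
    protein-DNA interface descriptors (buried area, hydrogen bonds, salt
    bridges, hydrophobic contacts). Includes a seeded synthetic coarse-grained
    generator of nucleosomal DNA structures and trajectories with injectable
    deformation schedules, so every analysis stage is testable against known
    ground truth without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
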