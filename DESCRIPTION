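Package: wbridge
Title: Energy-Based Hydrogen-Bond and Water-Bridge Analysis of Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of multi-model PDB trajectories for hydrogen-bond
    and water-bridge statistics between two solute species (for example a
    glycosaminoglycan chain and phospholipid headgroups). Hydrogen bonds are
    scored by an energy criterion combining a clamped hydrogen-acceptor
    distance term with two piecewise-linear angular scaling factors, and
    detected above a fixed energy threshold. The package identifies single
    waters bridging both solutes, aggregates unique donor-acceptor contact
    maps with percentage legends, estimates bond and bridge durations from
    frame occupancy, and tracks solvent-accessible surface area by a
    deterministic Shrake-Rupley rolling-probe estimate. A synthetic-fixture
    generator plants hydrogen bonds, water bridges and kinetic on/off
    patterns with a ground-truth manifest so every analysis stage is
    testable without large simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
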