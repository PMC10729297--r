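Package: plasmidforge
Title: Compile Combinatorial DNA Assembly Designs into Liquid-Handler
    Instructions and Track Plasmid Build Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns combinatorial DNA assembly designs (j5-style oligo,
    fragment and target-construct tables) into executable build
    instructions for automated liquid handlers: vendor oligo order
    sheets, acoustic-dispenser PCR setup picklists, thermocycler
    groupings, bench worklists for consolidation, bead purification,
    DpnI digestion and agar plating, and equivolume or equimolar
    assembly mixes. Tracks a build campaign end to end: capillary
    electrophoresis peak tables are scored against expected product
    sizes, failed PCRs are rolled into redo rounds, feasible constructs
    are computed from verified fragments, colony-picker output and
    sequencing verdicts are ingested, and verified constructs are
    cherry-picked into minimal archive plates with a per-stage funnel
    report. A seeded campaign simulator generates designs, peak tables,
    picker files and sequencing verdicts with realistic stage attrition
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
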