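# plasmidforge

Compile combinatorial DNA-assembly designs into liquid-handler
instructions, and track a plasmid build campaign from oligo ordering to
a freezer box of sequence-verified constructs.

## Who this is for

Groups running overlap-directed plasmid assembly (yeast homologous
recombination, Gibson-style chemistry) at 96-well scale and above. A
combinatorial design — DNA parts arranged in bins, one part per bin per
target construct, adjacent parts sharing exact homology arms — comes out
of an upstream primer/fragment design tool as a set of tables. Everything
between those tables and a verified construct library is mechanical and
error-prone: replicate demand for reused fragments, acoustic-dispenser
picklists, thermocycler groupings, capillary-electrophoresis QC against
expected product sizes, redo rounds, assembly mixes, colony registries,
sequencing submission sheets and cherry-pick consolidation.
`plasmidforge` does that translation and bookkeeping deterministically,
and validates every picklist by simulation before emitting it.

## The core quantities

* **Expected assembly**: for ordered fragments with lengths `L_i` and
  junction overlaps `o_j`, the assembled size is `S = Σ L_i − Σ o_j`
  (n junctions when circular, n−1 when linear); junctions are verified
  by exact suffix/prefix comparison over at least the campaign homology
  length (default 60 bp).
* **Replicate demand**: a fragment used in `u` constructs with a
  capacity of `c` assembly uses per PCR needs `⌈u/c⌉` replicate
  reactions.
* **Equimolar mixing**: `v_i = f · MW(L_i) / c_i` with
  `MW(L) = 617.96·L + 36.04` g/mol (dsDNA average), for target `f` fmol
  at `c_i` ng/µL, rounded up to the dispenser's droplet quantum.
  Reference: 1000 bp at 50 ng/µL, 10 fmol, 2.5 nL quantum → 125 nL.
* **QC calls**: a reaction passes when a lane peak sits within 10%
  relative size error at ≥ 1 ng/µL (both configurable); failures roll
  into redo rounds (default budget 6); a construct is feasible iff all
  its fragments verified.
* **Funnel**: per-stage counts and conditional survival rates down to
  overall success = unique verified / designed.

A seeded campaign simulator (`campaign_config`, `generate_design`,
`simulate_campaign`, `run_campaign`) generates designs, peak tables,
colony-picker files and sequencing verdicts with realistic stage
attrition, so the whole pipeline is testable offline. See the methods
vignette (`vignettes/build-campaign-methods.Rmd`) for the model, its
assumptions and its limitations.

## Worked example

```r
library(plasmidforge)

cfg <- campaign_config(n_bins = 3, parts_per_bin = c(2, 3, 4),
                       fragment_length_range = c(1000, 2000),
                       homology_bp = 60, seed = 42)
design <- generate_design(cfg)
design
#> <pf_design> sim_design_seed42: 9 parts in 3 bins, 18 oligos,
#>   9 fragments, 24 constructs (homology 60 bp)

sum(demand_plan(design, cfg$capacity_uses_per_reaction)$n_reactions)
#> [1] 20

expected_assembly(design, "pl01")$size_bp
#> [1] 5044

state <- run_campaign(design, simulate_campaign(design, cfg), cfg)
funnel_report(state)$counts
#>                  stage count
#>               designed    24
#>     fragments_demanded     9
#>          reactions_run    53
#>     fragments_verified     8
#>               feasible    12
#>        assembly_growth     9
#>  transformation_growth     7
#>        colonies_picked    21
#>        colony_pcr_pass     9
#>              sequenced     9
#>          fully_covered     6
#>          zero_mutation     1
#>        unique_verified     1
```

Reading the funnel: 9 unique fragments needed 20 planned reactions
(reused fragments get replicates) and 53 total attempts across redo
rounds; 8 of 9 fragments verified, leaving 12 of 24 constructs feasible;
attrition through yeast growth, transformation, colony PCR and
sequencing left 1 verified construct — overall success 4.2% for this
small noisy campaign.

A thin command-line wrapper over the same functions ships in
`inst/cli/plasmidforge.R`
(`simulate | parse | demand | order | qc | report`).

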