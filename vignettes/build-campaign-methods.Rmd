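---
title: "Compiling combinatorial assembly designs into build campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling combinatorial assembly designs into build campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidforge)
```

## The problem

High-throughput plasmid construction builds hundreds of constructs in one
batch by combinatorial assembly: DNA parts are arranged in *bins* (vector,
promoter/loading module, extension module, termination module, ...), a
target construct picks one part per bin, and adjacent parts carry exact
homologous overlaps so that overlap-directed assembly (e.g. yeast
homologous recombination of PCR products) stitches them into a circular
plasmid. An upstream design tool chooses primers and fragments; what
remains — and what this package does — is the unglamorous but
error-prone translation of that design into instrument instructions, and
the bookkeeping of a campaign as it attrites through PCR, assembly,
transformation, colony picking and sequencing.

`plasmidforge` is organised around five cooperating layers:

1. **Design I/O** (`parse_design`, `write_design`, `expected_assembly`,
   `export_expected_sequences`): a referentially checked design object
   and the expected sequence/size of every construct.
2. **Plate model** (`allocate_wells`, `quadrant_map`, `apply_transfers`,
   `write_picklist`): labware geometry, deterministic layout
   allocation, and a volume-accounting simulator every picklist must
   pass before it is emitted.
3. **Instruction compiler** (`demand_plan`, `purchase_order`,
   `pcr_setup`, `thermocycler_groups`, `equimolar_volumes`,
   `assembly_picklists`, `bench_worklist`).
4. **QC and tracking** (`parse_peak_table`, `call_reactions`,
   `fragment_status`, `redo_plan`, `feasible_constructs`,
   `register_colonies`, `ingest_ngs`, `consolidate_constructs`,
   `funnel_report`).
5. **Campaign simulator** (`campaign_config`, `generate_design`,
   `simulate_campaign`, `run_campaign`): seeded synthetic campaigns that
   exercise every stage without instrument data.

## Assembly arithmetic

Fragments physically contain their homology arms, so overlaps are counted
*inside* fragment length. For an ordered fragment list with junction
overlaps $o_j$, the expected assembled size is

$$ S \;=\; \sum_i L_i \;-\; \sum_j o_j, $$

with $n$ junctions for $n$ fragments when the construct is circular
(plasmids, the default) and $n - 1$ when linear. `expected_assembly`
verifies each junction by exact string comparison (suffix of one fragment
= prefix of the next over at least the campaign homology length, 60 bp by
default) and emits each shared overlap once; a mismatch is a junction
error naming the offending pair rather than a silently wrong sequence.

## Demand, layout and liquid handling

A part reused across many constructs needs replicate PCRs: with a
capacity of $c$ assembly uses per reaction (default 4, configurable per
campaign), a fragment appearing in $u$ constructs needs
$\lceil u / c \rceil$ replicates. Layout allocation is strictly
sequential (sample $i$ lands at index $i$), which makes layouts
deterministic, stable under appends, and pigeonholed across plates.

Acoustic dispensers move fixed droplet quanta, so every emitted volume is
snapped to the quantum — **up** where a molar floor matters (equimolar
mixes, recipe volumes), **down** where overflow matters (equivolume
fills). The default quantum is 25 nL for PCR setup and 2.5 nL for
assembly mixes; both are arguments, as are all labware capacities and
dead volumes (`labware_specs`, overridable from YAML).

Every compiled picklist is validated by simulation before it is emitted:
`apply_transfers` walks the transfers in order against the declared
source plates, requiring each source well to retain its dead volume and
each destination to stay within capacity, and a single violation aborts
the whole batch with the well and shortfall named. Total liquid is
conserved by construction; the test suite asserts this over randomized
campaigns.

Equimolar mixing converts a molar target to volume with the average
double-stranded DNA molecular weight
$\mathrm{MW}(L) = 617.96\,L + 36.04$ g/mol:
$v_i = f \cdot \mathrm{MW}(L_i) / c_i$ for target $f$ fmol at
concentration $c_i$ ng/µL. The worked reference — 1000 bp at 50 ng/µL,
10 fmol, 2.5 nL quantum — gives 123.599 nL, rounded up to 125 nL. A
`vector_excess` multiplier over-supplies the backbone when desired
(default 1, true equimolar); if part volumes alone exceed the reaction
total the compiler errors instead of silently rescaling.

Thermocycler grouping is greedy span-limited clustering on annealing
temperature (new group when the span would exceed 2 °C); when a block
budget caps the group count below the greedy result, an exact dynamic
program finds the contiguous partition minimizing the largest
within-group span — the tests check it against exhaustive search at
small sizes. Extension time is sized for the largest product in the
group at 30 s per kb, rounded up.

## QC calls and redo rounds

A capillary-electrophoresis lane passes for a reaction when some peak
lies within a relative size tolerance (default 10%) at or above a
minimum concentration (default 1 ng/µL); the matched peak minimizes
relative error, ties broken toward higher concentration, and an empty
lane is distinguished from an off-size failure. Alignment-marker sizes
are stripped at parse time from a configured list, and unparseable rows
are set aside and reported, never dropped. Neither threshold is stated
by typical instrument vendors as a universal constant, so both are
arguments logged with every call.

Failed reactions roll into the next round with a fresh consolidated
layout — conditions copied verbatim, or ±2 °C alternating under the
gradient strategy — up to six rounds by default. The redo set and the
passing set partition each round exactly (a property test), and a
fragment is `verified` (any replicate passed), `exhausted` (all rounds
consumed) or `pending`. Feasibility is then pure set logic: a construct
is buildable iff every fragment on its list is verified, which is
monotone in the verified set.

## Tracking, verdicts and consolidation

Colony-picker output maps agar positions to culture wells; joined
against the plating layout it yields the colony registry (three picks
per construct by default; over-picked rows are kept with a warning,
because pickers do over-pick, while culture-well collisions are hard
errors). Colony PCR across the insert region is scored with the same
call machinery, using the insert-chain size (all non-vector fragments,
junctions deduplicated) as the expected product. A sequencing verdict
qualifies a colony under the default policy of full coverage and zero
mutations (both thresholds configurable); a construct is verified when
any colony qualifies. Consolidation cherry-picks exactly one qualifying
colony per verified construct — the lowest (plate, well-index) position,
a deterministic tie-break — onto minimally many archive plates, and is
idempotent. The funnel report gives per-stage counts, conditional
survival rates and the overall success rate (unique verified /
designed), with construct-level counts non-increasing by construction.

State is persisted as versioned JSON snapshots rather than a database:
the campaign is desk-scale, and diff-able provenance is worth more than
query power. Forward-only provenance (no stage referencing an entity
absent upstream) is asserted on load and at the end of every pipeline
run.

## What the simulator emulates — and what it does not

`generate_design` draws one random homology sequence per junction and
gives every part its flanking arms, so all junctions validate by
construction; the target set is the full factorial over bins. The
default configuration is 4 bins of 2 × 7 × 7 × 9 parts — 882 target
constructs, the scale of a large published build campaign — with 1.5–3.5
kb fragments (4-fragment plasmids of roughly 6–14 kb) and 60 bp
overlaps.

`simulate_campaign` draws one latent Bernoulli outcome per unit at each
stage, with default rates taken from that campaign's empirical
attrition: PCR lineage success 0.88, yeast assembly growth 0.66,
*E. coli* transformation growth 0.70, colony-PCR pass 0.41, full
sequencing coverage 0.76, zero mutations 0.65. A succeeding PCR lineage
shows its band from a front-loaded (truncated-geometric) success round
onward; before that, and for failing lineages, the lane shows an empty
well, an off-size artifact or a sub-threshold band. Observed peak sizes
carry relative Gaussian noise (sd 0.03), which at the 10% call tolerance
implies a false-fail probability of about $2\Phi(-0.10/0.03) \approx
9\times10^{-4}$ — the suite measures it below 1% over $10^4$ lanes.

Two deliberate simplifications bound what passing tests show about real
data. First, failures are independent across reactions and stages; real
campaigns share failure modes through templates, GC content and
batch effects, so real attrition is over-dispersed relative to the
simulator. Second, a single full-factorial design reuses each fragment
in many constructs, far more than a real merged multi-design batch
reuses its several hundred unique fragments; fragment-level verification
therefore saturates at default scale and the simulated overall success
(~22–24%) exceeds what a campaign with hundreds of lightly reused
fragments achieves. The simulator is a test harness for the *machinery*
— calls, partitions, layouts, conservation, tracking — not a predictive
model of campaign yield.

In the perfect-information limit (all stage probabilities 1, zero size
noise) the pipeline must and does recover the ground truth exactly:
every funnel rate is 1 and every designed construct is verified, across
seeds. Under default rates, pooled per-stage survival over hundreds of
seeded 24-construct campaigns sits within three Monte-Carlo standard
errors of the configured probabilities.

## Numerical and interface choices

* Volumes are snapped to the droplet quantum with a `round(x/q, 9)`
  guard so float error never flips a boundary; volume comparisons use a
  1 nL-scale epsilon.
* Sequences are upper-cased and whitespace-stripped on ingest; addresses
  accept `A1` and `A01` and emit unpadded.
* Bundle tables are canonically ordered by id, making writes
  byte-deterministic under a fixed seed and round-trips exact.
* Problem sizes in the test suite (24-construct campaigns, 500 small
  random designs, 500 simulation seeds) were chosen to exercise every
  code path with comfortable statistical power at desk-scale runtime.
* XLSX order sheets are not emitted — order sheets are CSV in the vendor
  96-well upload shape (`Plate, Well, Name, Sequence`).
* The command-line interface (`inst/cli/plasmidforge.R`) is a thin
  wrapper over the exported functions; the functions themselves are the
  primary surface.

## Worked example

```{r example}
cfg <- campaign_config(n_bins = 3, parts_per_bin = c(2, 3, 4),
                       fragment_length_range = c(1000, 2000),
                       homology_bp = 60, seed = 42)
design <- generate_design(cfg)
design

plan <- demand_plan(design, cfg$capacity_uses_per_reaction)
sum(plan$n_reactions)

sim <- simulate_campaign(design, cfg)
state <- run_campaign(design, sim, cfg)
report <- funnel_report(state)
report$counts
round(report$overall_success, 3)
```
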