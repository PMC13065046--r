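---
title: "memflux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memflux)
```

memflux analyses molecular-dynamics trajectories of membrane pumps and
multi-copy aggregation systems. It answers four questions that recur when a
small transmembrane regulator (a "regulin", such as phospholamban, or a
candidate like neuronatin) is studied against a P-type Ca²⁺ pump such as
SERCA2b:

1. **Water translocation** — of the waters that enter the protein volume,
   what fraction exits on the opposite side of the bilayer?
2. **Water wires** — how long are the hydrogen-bonded chains of water inside
   the protein volume, per frame?
3. **Interface contacts** — which inter-chain salt bridges and hydrogen
   bonds persist, and for what fraction of frames (occupancy)?
4. **Aggregation** — when several protein copies diffuse in a periodic box,
   how does the number of separate "entities" (contact-connected groups of
   copies) evolve?

It also carries the supporting structural observables these studies lean on:
Kabsch superposition and RMSD series, radius of gyration, Shrake–Rupley
solvent-accessible surface area, and RMSD-matrix clustering of frames with
medoid extraction.

## Data model and conventions

A trajectory (`mdtrj`) is an atom table plus an `n_frames × n_atoms × 3`
coordinate array in ångström, an optional per-frame **orthorhombic** box
(Lx, Ly, Lz), and optional frame times in nanoseconds. Triclinic cells are
refused explicitly rather than silently mishandled. Waters are recognised by
a configurable residue-name whitelist (`HOH`, `WAT`, `SOL`, `TIP3` by
default), which is robust across force fields without topology perception.

All indices — atoms and frames — are **1-based**, matching R semantics
throughout the code and its outputs; command-line reports therefore need no
translation layer. Internal units are fixed: ångström for length,
nanosecond for time, degrees for angles.

Multi-model PDB is the interchange format (one frame per `MODEL`,
`CRYST1` for the box); binary DCD trajectories are ingested through the
established bio3d reader against a PDB topology with an atom-count check.
Every analysis serialises to a tibble carrying a provenance block (inputs,
parameters, seed, package version), written to TSV (`#`-prefixed provenance
header) or JSON. Provenance deliberately contains **no timestamps**, so a
run with a fixed seed reproduces its artifacts byte for byte.

## The protein volume and permeation events

"Inside the protein volume" is deliberately operational: a water oxygen is
inside at a frame iff

* its *z* lies in the closed slab interval `[z_lower, z_upper]` — the
  hydrophobic core of the bilayer, either given directly or estimated as
  the per-leaflet (optionally trimmed) mean *z* of marker atoms such as
  lipid phosphorus — **and**
* its minimum distance to any protein heavy atom is ≤ a proximity cutoff
  (default 6.0 Å; minimum-image when a box is present).

A slab-bounded proximity shell was chosen over per-frame convex hulls or
grid pockets because it is cheap, deterministic, and the standard shape of
channel-water selections; the cutoff is exposed everywhere.

Event semantics: an event **opens** at the first frame a water is inside
after being outside; its entry side is read from the water's position at the
last outside frame (`lower` if *z* is below the slab, `upper` if above; a
water that is laterally outside while inside the slab *z*-range is
attributed to the nearest slab boundary, since the statistic needs a binary
side). The event **closes** at the first subsequent outside frame, with the
exit side assigned the same way. Outcomes are `crossed` (exit side ≠ entry
side), `returned` (same side) and `unresolved` (still inside at the final
frame). One water may generate several events. Waters already inside at
frame 1 open no event until they first leave: with no observed entry there
is no defensible entry side.

The translocation success rate is

$$\mathrm{rate} = \frac{n_\mathrm{crossed}}{n_\mathrm{crossed} + n_\mathrm{returned}}$$

Unresolved events are excluded from the denominator — a water still inside
at trajectory end has no outcome — and reported separately so the reader can
judge censoring. With zero resolved events the rate is `NA`, never 0.
Single-frame excursions count by default (no debouncing); a `min_dwell`
parameter smooths them away when the sampling interval makes that
appropriate. Whether published percentages of this kind pool replicas or
average per-replica rates is often unstated, so `translocation_rate()` and
`replica_merge()` emit **both** the pooled rate (counts summed before
dividing) and the unweighted mean of per-replica rates; the two agree
exactly when replicas contribute equal event counts.

## Water wires

Within each frame, nodes are the in-volume water oxygens (same membership
rule as permeation) and edges are hydrogen bonds: O–O distance ≤ 3.5 Å and,
when hydrogens are available, some D–H···A angle (measured at the hydrogen,
in either donor direction) ≥ 150°. These are the canonical geometric
criteria for water hydrogen bonds in trajectory analysis; both are
parameters. Distance-only mode (for hydrogen-free models) is a strict
superset of the angular definition and is flagged in provenance.

A **wire** is a connected component with at least two molecules, and its
length is the number of molecules on the component's longest simple path —
so a dimer has length 2, and "chain" ambiguity (path vs component) is
resolved toward paths while the component size is also reported. Longest
simple path is NP-hard in general; components of ≤ 15 nodes (the practical
regime for channel waters) are solved exactly by exhaustive depth-first
search, larger ones get a double-sweep BFS lower bound flagged
`approx = TRUE`. Per frame the maximum and the mean wire length are
reported; frames with no wires are recorded as missing, not zero, so that
histograms are not distorted by empty frames.

## Interface contacts and occupancy

A salt bridge is present at a frame iff the minimum distance between the
side-chain charged-group heavy atoms is ≤ 4.0 Å (the common
Barlow–Thornton-style convention; configurable). Anionic groups cover
Asp/Glu carboxylates **and phosphoserine phosphate oxygens**, so
phosphorylated systems are expressible without special cases; cationic
groups cover Arg/Lys/His side-chain nitrogens. Hydrogen bonds between
chains use the water-wire criteria on polar N/O heavy atoms. Occupancy is
simply the fraction of analysed frames (after any stride) in which the
contact is present — which makes it frame-permutation invariant and
monotone in the cutoff, two properties the test suite enforces.
`interaction_inventory()` scans all cross-chain candidate pairs and reports
those at or above an occupancy threshold (default 0.2), descending.

## Aggregation entities

Copies are tagged by chain (or an explicit mapping). Two copies *interact*
at a frame iff their minimum heavy-atom distance is ≤ 4.5 Å — a standard
non-bonded contact convention; because the threshold is a convention, an
entity-count sensitivity series over {4.0, 4.5, 5.0} Å is emitted by
default. An **entity** is a connected component of this copy-contact graph:
a single copy or a group of copies, each copy in exactly one entity.

Under periodic boundaries two precautions matter. First, each copy is made
whole before any distance: every atom is shifted by the minimum image
relative to the copy's first atom, since a copy split across the boundary
would corrupt minimum distances. Second, inter-copy distances themselves use
the per-component minimum image on the orthorhombic box, so contacts formed
across the boundary are found; the tests verify this against an explicit
27-image search. `time_to_single_entity` is the first time (ns when frame
times exist, else the frame index) with a single entity, `NA` when full
aggregation is never reached — both outcomes are first-class, since published
systems show full aggregation within a few hundred nanoseconds in all-atom
runs but incomplete aggregation in coarse-grained ones. Coarse-grained bead
trajectories are handled identically (beads are treated as heavy atoms).

Stable entity labels for plotting persist across frames by maximal-overlap
matching: an entity inherits the label of the predecessor sharing most
copies, merges keep the larger predecessor's label, overlap ties go to the
predecessor holding the lowest copy id, and a contested label after a split
stays with the larger fragment.

## Structural observables

**Kabsch superposition** minimises weighted RMSD via the SVD of the
covariance matrix with sign correction of the smallest singular value, so
the rotation is always proper (det = +1, no reflection). Collinear or
sub-3-point sets are solved but flagged `degenerate` (the rotation is not
unique). `rmsd_series()` aligns on one selection and measures on another,
supporting e.g. cytoplasmic-domain RMSD after alignment on transmembrane
helices.

**Clustering**: frames are clustered by average-linkage hierarchical
clustering on the pairwise Kabsch-aligned RMSD matrix, cut at `k` clusters
or height `h`. The linkage is a toolkit choice (the upstream procedure this
mirrors ran in a commercial suite that does not document one): average
linkage is deterministic and standard for MD frames. The representative
structure is the **medoid of the most populated cluster** — the member frame
minimising summed RMSD to its co-members, not a centroid, so it is always a
real frame. Every tie (most-populated cluster, medoid) breaks to the lowest
frame index, making results reproducible to the byte.

**SASA** uses Shrake–Rupley quadrature with a *deterministic* golden-spiral
point set (default 960 points, probe 1.4 Å) rather than random sphere
points, trading a negligible quadrature bias for exact reproducibility.
Radii default to Bondi-style values (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20, P 1.80 Å; unknown elements 1.70). The isolated-sphere value is
exact under this quadrature; on occluded pairs the error falls well below
0.5 % at the default point count and shrinks as points are added.

**Radius of gyration** is the mass-weighted root-mean-square distance from
the centre of mass.

## Synthetic systems and what they do (not) show

No trajectories are shipped; the `generate_*()` functions build them with
planted ground truth, and their defaults are the study conditions the test
suite runs at:

* `generate_permeation_system()` — a static cylindrical dummy channel
  spanning a (−15, +15) Å slab in a 60×60×80 Å box; each scripted water
  follows a piecewise-linear path realising its outcome
  (`crossed`/`returned`/`unresolved`), background waters stay outside the
  volume. The acceptance conditions plant 200 events, the order of entries
  observed per system in the studies this mirrors.
* `generate_wire_frames()` — in-volume chains at 2.8 Å O–O spacing with the
  donor hydrogen on the O–O axis (ideal 180° D–H···A), isolated decoys, and
  chain lengths 2–9 (9 being the extreme a published distribution reaches).
* `generate_aggregation_trajectory()` — seven rigid dummy copies on
  well-separated lattice slots of a 90 Å periodic box, joined into contact
  chains at scripted merge frames; optionally one pair touches only across
  the boundary, detectable solely by minimum image.
* `generate_cluster_frames()` — frames drawn from planted conformations
  (consecutive pairs constructed at a target aligned RMSD of 8 Å by
  root-finding a displacement scale) plus isotropic 0.2 Å noise and random
  rigid motions, so recovery requires alignment.
* `generate_contact_trajectory()` — a glutamate–arginine (or
  phosphoserine–arginine) pair held at 3.7 Å in scripted frames and 9 Å
  otherwise; the planted schedules of 74/100 and 56/100 frames mirror the
  occupancy-comparison format used for phosphorylation effects.

Each generator runs on an isolated seeded RNG stream (the caller's RNG
state is untouched) and is byte-deterministic given its seed; systems are
written as multi-model PDB so tests exercise the full I/O path.

These systems carry the *geometric* structure each analysis assumes —
nothing more. They have no force field, no thermodynamics, no realistic
water density, and no conformational coupling between observables. A
passing suite therefore demonstrates that the statistics are computed
correctly on trajectories whose answers are known; it does not validate any
biological claim about a real pump or aggregate, and published headline
percentages from microsecond simulations of large membrane systems are not
reproducible at this scale. Problem sizes in the tests (tens of frames,
hundreds of atoms, 200 planted events, 500 random graphs, 200 random
contact frames) were chosen as the smallest systems that still exercise
every code path and tie-break.

## Numerical choices and degenerate inputs

* Closed slab interval; membership threshold comparisons are `≤`/`≥`.
* Zero resolved permeation events → rate `NA` with counts, never 0/0.
* Empty frames in wire statistics → `NA`, not 0.
* Kabsch on degenerate point sets → flagged, not refused (RMSD remains
  well-defined); fewer than 1 point is an error.
* `estimate_slab()` refuses marker sets lying on one side of their mean.
* Aggregation with `use_pbc = TRUE` and no box is an error, not a silent
  fallback.
* All tie-breaks (medoid, most-populated cluster, entity labels, event
  sides at exact boundary distance) are specified and tested, so every
  result is deterministic given inputs and parameters.

## Interfaces

Every analysis is a plain R function taking a trajectory (or data frame)
first and returning a tibble or an object with `tidy()`/`glance()`/
`autoplot()` methods, so results chain with the pipe. The `exec/memflux`
script exposes the same runs as shell subcommands (`permeation`, `wires`,
`contacts`, `aggregate`, `rmsd`, `cluster`, `sasa`, `synth`) with a small
selection language (`chain A and resid 1-35 and name CA`); it contains no
logic of its own. Plotting is never load-bearing: figures are conveniences
over the same tables the writers emit.

## Known limitations

* Orthorhombic boxes only; triclinic input is refused.
* Water-only wires: protein donors/acceptors are not yet bridge nodes, so
  wires broken by a protein-mediated hydrogen bond appear as two wires.
* Wire lengths above 15-node components are lower bounds (flagged).
* No topology perception: bonds, protonation and charge states are inferred
  from residue/atom names, not chemistry.
* The permeation volume is a proximity shell, not a pore surface; waters
  skirting the protein within the slab count as "inside" if within the
  cutoff.
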