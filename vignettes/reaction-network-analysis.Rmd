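---
title: "Reaction network analysis of trajectory ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction network analysis of trajectory ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reanet)
```

reanet turns an ensemble of molecular geometry snapshots with energies into
a directed network of chemical species and thermodynamically feasible
transformations. This vignette explains the underlying models, the
parameters that matter, the numerical conventions, and what the synthetic
validation data do and do not demonstrate.

## The molecular-graph model

A snapshot is reduced to a labeled graph: atoms are vertices labeled by
element; edges are interatomic contacts classified by type. Perception is
purely geometric:

* **covalent** — both atoms outside the d-block and outside the
  alkali/alkaline-earth groups, distance at most `covalent_scale` times the
  sum of the two covalent radii;
* **organometallic** — exactly one atom a transition metal (d-block),
  distance at most `organometallic_scale` times the radius sum;
* **hydrogen bond** (opt-in) — a donor D in {N, O, F} carrying a covalent H,
  an acceptor A in {N, O, F}, D–A distance at most `hbond_max_da` and
  D–H···A angle at least `hbond_min_angle`;
* **ionic** (opt-in) — an alkali or alkaline-earth center within
  `ionic_max_dist` of O, N or a halogen.

The bundled radius table holds Cordero-type single-bond covalent radii for
H–Rn (low-spin values for Mn, Fe, Co). Defaults are `covalent_scale` and
`organometallic_scale` of 1.15 (a standard tolerance around equilibrium bond
lengths), `hbond_max_da` 3.5 Å, `hbond_min_angle` 120°, `ionic_max_dist`
3.0 Å. All are configuration parameters rather than fixed constants: the
method's contracts are threshold-parametric, and users working with unusual
coordination chemistry are expected to tune them. The default active types
are covalent + organometallic, which define species identity; hydrogen-bond
and ionic edges are intended for fragment-level aggregation analysis, where
activating them merges hydrogen-bonded or ion-paired clusters into single
fragments.

Deliberately excluded from the model: bond orders, formal charges,
aromaticity, and any electronic-structure information. Two geometries are
the same species exactly when their typed connectivity is the same. This
makes speciation robust against conformational noise but blind to, e.g.,
redox isomerism at fixed connectivity.

## Species identity: canonical fingerprints

Species are equivalence classes under element- and type-preserving graph
isomorphism. The fingerprint is a canonical certificate computed by
iterative color refinement: vertices start colored by element, and colors
are repeatedly replaced by (own color, sorted multiset of (edge type,
neighbor color)) until stable. If refinement ends with color ties — which
happens only on symmetric structures — the algorithm individualizes each
vertex of the first smallest tied class in turn, re-refines, and takes the
lexicographically smallest certificate over all branches. Branching over a
complete, isomorphism-invariant target cell makes the result independent of
input atom order; the cost is exponential only in the residual symmetry,
which is negligible for molecular graphs.

Two implementation routes exist deliberately: `fingerprint()` (the canonical
key, used for database lookup) and `is_isomorphic()` (VF2 with vertex and
edge colors, via igraph). The test suite certifies both against an
exhaustive-permutation oracle on random labeled graphs of up to 8 vertices —
small enough that all n! relabelings can be enumerated, large enough to
exercise nontrivial symmetry — and checks that the two routes always agree.

## Event identification

The walk over the trajectory is incremental: frame 1 initializes the species
database; each later frame is perceived, fingerprinted, and compared with
its predecessor. An unchanged pattern extends the current species' conformer
list; a changed one is looked up in the database — matching an earlier
species closes a directed edge back to the existing node (a revisit, so
A → B → A yields two species and two transitions, not three nodes) — or
founds a new species. The previous-frame check precedes the database lookup;
since fingerprint equality decides both, the outcome is identical either
way, but the two-step order keeps the common no-change case cheap and makes
the walk's logic explicit.

Each species records all its conformers (frame index, energy, geometry); its
node energy is the most stable conformer's, with ties broken by lowest frame
index. Parallel trajectories of the same system are analyzed independently
and merged on fingerprint keys (`merge_event_logs()`); no cross-trajectory
transitions are invented.

## Network assembly, trimming, styling

The network has one node per species and one directed edge per observed
(source, target) pair, with multiplicity counting repeated observations and
ΔE = E(target) − E(source) in kcal/mol. kcal/mol is the canonical internal
unit because feasibility thresholds are conventionally quoted in it; hartree
(× 627.5094740631) and eV (× 23.060548) inputs are converted on read.

Trimming takes three passes, in order:

1. nodes above `node_threshold` relative to the reference are deleted with
   all incident edges;
2. remaining edges with ΔE above `edge_threshold` are deleted;
3. nodes left without any incident edge are deleted (never the reference).

Both thresholds default to 25 kcal/mol, a conventional feasibility bound for
room-temperature solution chemistry. Three genuinely open design points are
resolved as follows:

* **Reference node.** Thresholds are only meaningful relative to a zero.
  The default reference is the global minimum-energy node; users should name
  the species of intact, noninteracting starting components when they have
  one. A reference sitting more than `node_threshold` above the network
  minimum is rejected as a configuration error rather than silently trimming
  everything below it.
* **Signed vs absolute ΔE.** Edge trimming uses signed (uphill) ΔE: a
  strongly downhill transformation is among the most probable and is never
  removed, whatever its magnitude.
* **"Inaccessible" nodes.** Pass 3 removes isolated nodes by default; the
  `prune_unreachable` option instead removes everything without a directed
  path from the reference. Both readings are defensible; isolated-only is
  the default because it is the more conservative edit.

Trimming is idempotent and always returns subsets of the input; these
invariants are property-tested on 1,000 random networks.

Styling maps node energies linearly to [0, 1] between the network's MIN and
MAX (color), and edge widths inversely between the extreme ΔE values, so the
most probable transformation is drawn thickest. When a range collapses
(single node energy value, single edge), everything maps to 0.5 — a declared
convention for the degenerate case. Conformer-energy spreads are summarized
as five-number statistics (quartiles by linear interpolation, R's default
quantile type 7) for boxplot annotation.

## Fragment analysis

Connected components of a snapshot graph under a chosen subset of
interaction types are found by breadth-first search; each component is one
fragment. Components are reported in order of smallest atom index, making
output deterministic. `unique_pivot_fragments()` scans a trajectory for
fragments containing at least one pivot atom (the anchoring transition
metal), deduplicates them by the same canonical fingerprint used for
whole-system speciation — guaranteeing consistency between the two
inventories — and reports occurrences and the minimum hosting-snapshot
energy. That energy is the whole snapshot's, not a per-fragment estimate:
partitioning a total energy over fragments has no well-defined answer
without electronic-structure input, so the total is reported and labeled as
such. A fragment with two or more pivot atoms is a single (multinuclear)
entry with its nuclearity in `n_pivot`; restricting interaction types can
only split fragments, never merge them.

## The synthetic generator: what it emulates, and what not

`generate_trajectory()` emulates the one property of a metadynamics ensemble
that the analysis pipeline consumes: a sequence of frames whose bonding
pattern changes at known places. A toy complex (by default one Mn center
with up to six monoatomic ligands of distinct elements on octahedral axes)
is edited at programmed frames — dissociation, association, ligand exchange,
unit merging — by radial displacement of the affected atoms; bonded contacts
sit at 0.92× the perception cutoff and detached ones at 1.8×, placing both
comfortably on their side of the threshold. Between events, coordinates get
Gaussian jitter (default σ = 0.02 Å).

Two safeguards make the ground truth trustworthy rather than assumed:
`jitter_sigma` must stay below a quarter of the smallest |distance − cutoff|
slack over all atom pairs (checked per frame on the noiseless geometry), and
every emitted frame's perceived graph is compared against the intended one,
with generation failing loudly on any mismatch. Energies are assigned, not
computed: each ground-truth species draws a baseline from N(0, 10 kcal/mol)
and each conformer adds N(0, 1 kcal/mol) — spreads chosen to resemble the
few-kcal/mol conformer windows and tens-of-kcal/mol species separations of
real organometallic ensembles — so trimming and boxplot statistics can be
verified against known values. Everything is deterministic given the seed.

What passing on such data shows: bond perception, canonicalization,
event logging, network assembly, trimming and fragment inventory are correct
at the graph level, including revisit re-identification and
within/across-snapshot deduplication. What it does not show: correctness of
the distance criteria for any particular chemistry (real trajectories have
continuous bond-breaking geometries that sit near cutoffs, transient
contacts, and correlated motion none of which the generator produces), nor
anything about the physical accuracy of input energies, which the tool takes
as given. Ligands in the random schedules are chosen with pairwise distinct
elements so that programmed edits are guaranteed non-isomorphic and the
ground-truth species count is unambiguous.

## Numerical conventions and degenerate inputs

* Energies parse from the first float-like token on the XYZ comment line
  (splitting on whitespace and `=`, skipping pure integers); frames without
  one are kept for speciation but excluded from trimming and styling, with a
  warning.
* Atom indices are frame positions; all graphs and fragments refer to atoms
  by position.
* Conformer export orders by energy, then first-seen frame (stable
  tie-break).
* GraphML export writes doubles at full precision (`%.17g`) so topology,
  energies, ΔE and multiplicities round-trip exactly; XYZ coordinates are
  written to 10 decimal places (round-trip error below 10⁻⁶ Å).
* Empty ensembles, unknown element symbols, non-finite coordinates,
  mismatched element lists across frames, and empty species records are
  rejected with specific errors rather than propagated.

## Validation problem sizes

The shipped test suite and the acceptance script validate at these scales,
chosen to exhaust the relevant behavior while keeping a full run in minutes
on one CPU: 200 random labeled graphs of 2–8 vertices (all ~20,000 pairs
against the exhaustive-permutation oracle), 100 random event schedules of
1–5 events over 5–50 frames with exact ground-truth recovery required,
1,000 random networks for trimming invariants, 50 for style monotonicity,
and random graphs of up to 30 vertices against a union-find partition
oracle.

## Known limitations

* Speciation is connectivity-only: conformers, stereoisomers and redox
  states at fixed connectivity are one species by design.
* Thermodynamic edges only: ΔE between minima, no transition states, no
  barriers, no kinetics.
* Distance-based perception misclassifies near-cutoff geometries; scales
  must be tuned for exotic coordination environments, and the defaults are
  declared values, not fitted ones.
* The canonical-labeling worst case is exponential in residual graph
  symmetry; molecular graphs are benign, but adversarial regular graphs
  with uniform labels would be slow.
* Fragment energies are whole-snapshot energies (see above).
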