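# reanet

Graph-theoretical reaction network analysis of molecular trajectory
ensembles.

## The problem

Exploring the reactivity of a homogeneous catalytic mixture — catalyst
precursor, ligands, substrates, additives, solvent — produces large ensembles
of geometry snapshots (e.g. from metadynamics conformer exploration), in
which chemical transformations appear as changes of bonding pattern between
frames. Finding the distinct chemical species in such an ensemble, the
transformations connecting them, and the subset of both that is
thermodynamically accessible is tedious and bias-prone by hand. reanet
automates it for computational chemists working on catalyst activation and
deactivation, speciation in multicomponent mixtures, and multinuclear
cluster formation.

## The method

Each snapshot *I<sub>i</sub>* (elements, Cartesian coordinates in Å, energy
in kcal/mol) is converted into a labeled molecular graph *G<sub>i</sub>*:
vertices are atoms labeled by element; edges are typed interactions
perceived from interatomic distances against scaled covalent-radius sums —
covalent (nonmetal–nonmetal, *d* ≤ *s*·(r<sub>i</sub>+r<sub>j</sub>)),
organometallic (transition-metal–nonmetal), and opt-in hydrogen-bond and
ionic contacts. Species identity is connectivity only: no bond orders, no
formal charges.

Walking the trajectory, each *G<sub>i</sub>* is tested for isomorphism
against *G<sub>i−1</sub>*; on a change it is matched against the database of
known species via a canonical fingerprint (color refinement with
individualization on ties), so revisited species are re-identified rather
than duplicated, and each change is logged as a directed transition. The
species and transitions form a directed reaction network: node energy is the
most stable conformer's, an edge carries the transformation energy
ΔE = E(target) − E(source) and its observed multiplicity.

The network is then trimmed to the thermodynamically feasible subnetwork:
nodes more than a threshold (default 25 kcal/mol) above the reference
species are deleted with all incident edges, remaining edges with ΔE above
the edge threshold are deleted, and stranded nodes are pruned. Style
mappings (node color from min–max energy, edge width inverse in ΔE) and
five-number conformer-energy summaries support visualization. For
multi-metal systems, breadth-first-search connected components anchored on a
pivot element (e.g. Mn) inventory the unique mono- and multinuclear
fragments across the trajectory.

A synthetic trajectory generator with programmed events (dissociation,
association, ligand exchange, dimerization) and assigned energies provides
ground-truth ensembles; it self-certifies every emitted frame against the
bond-perception oracle.

## Worked example

```r
library(reanet)

# a toy Mn complex; three programmed events: N dissociates at frame 5,
# P associates at frame 10, O is exchanged for N at frame 15
base <- toy_complex(ligands = c("N", "O", "F", "P"),
                    bonded = c(TRUE, TRUE, TRUE, FALSE))
sched <- event_schedule(base, events = list(
  list(frame = 5,  type = "break_bond",  i = 1L, j = 2L),
  list(frame = 10, type = "form_bond",   i = 1L, j = 5L),
  list(frame = 15, type = "swap_ligand", i = 1L, j = 3L, k = 2L)), seed = 42)
res <- generate_trajectory(sched, 20)

log <- analyze_trajectory(res$ensemble)
species_table(log)
#>        fingerprint n_conformers node_energy      e_min  e_median     e_max
#> 1 6914842d8391f17a            4  13.6034600 13.6034600 13.864389 15.221106
#> 2 8788417374538543            5  -7.0358424 -7.0358424 -4.342112 -3.360336
#> 3 75df541f7d1c748c            5   0.9748287  0.9748287  3.352495  4.267235
#> 4 608d452d7ec73f29            6   3.8881591  3.8881591  6.089348  7.648739

net <- build_network(log)
net$edges[, c("delta_e", "multiplicity")]
#>      delta_e multiplicity
#> 1 -20.639302            1
#> 2   8.010671            1
#> 3   2.913330            1

trim_network(net, trim_config(node_threshold = 25, edge_threshold = 25))
#> <reaction network: 4 node(s), 3 edge(s), E in [-7.035842, 13.60346] kcal/mol>
```

Four species are found (the starting complex plus one per event; energies
are the generator's assigned values in kcal/mol), connected by three
transitions. The first transformation is 20.6 kcal/mol downhill (the most
probable edge — it would be drawn thickest); with both thresholds at
25 kcal/mol relative to the most stable species nothing is trimmed here.
`write_network(net, "net.graphml")` exports the network with energies and
style values; `unique_pivot_fragments(ens, pivot_element = "Mn")` lists the
unique metal fragments of a multi-metal trajectory.

The same pipeline runs from the shell on any multi-frame XYZ file with
per-frame energies on the comment lines:

```sh
reanet analyze   --traj traj.xyz --energy-unit hartree
reanet network   --traj traj.xyz --node-thr 25 --edge-thr 25 --out net.graphml
reanet fragments --traj traj.xyz --pivot Mn --out fragments.csv
reanet synth     --schedule schedule.yaml --out traj.xyz --truth truth.json
```

(the script installs to `system.file("exec", "reanet", package = "reanet")`).

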