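# psnet — ensemble analysis of protein structure networks

`psnet` is an R package for analyzing conformational ensembles of proteins
as residue interaction networks, in the tradition of allosteric-communication
studies on multi-domain chaperones and enzymes.  Given an ensemble (a
multi-model PDB, typically snapshots of a molecular-dynamics trajectory), it
computes, per residue and per contact:

- **Force-constant rigidity profiles** from inter-residue distance
  fluctuations, `k_i = 3 k_B T / Var(d_i)`, where `d_i` is the mean distance
  of residue *i* to all non-neighbor residues — high `k_i` marks
  structurally rigid residues such as inter-domain hinges; plus computed
  B-factors and sphere-point residue-depth (solvent protection) profiles.
- **Dynamic cross-correlation matrices** `C_ij ∈ [−1, 1]`, principal modes
  of the coordinate covariance, and mode-averaged mobility profiles.
- **Protein structure networks**: residues are nodes, and an edge is drawn
  when the normalized side-chain contact strength
  `I_ij = 100 · n_ij / sqrt(N_i N_j)` exceeds `I_min` (default 3%, with a
  largest-cluster scan to locate the percolation-style transition);
  over an ensemble, edges are *dynamically stable* when present in more
  than 75% of snapshots.  Hubs are nodes of degree ≥ 4.
- **k-clique percolation communities** (k = 3, 4; strict `k−1` or relaxed
  `k−1 or k−2` adjacency) on the stable network, with per-community
  simultaneous-presence fractions.
- **Allosteric communication measures** on the correlation-weighted graph
  `w_ij = −ln|C_ij|`: all-pairs shortest paths (Floyd–Warshall with
  path counting), normalized betweenness, and ensembles of suboptimal
  paths within a length tolerance (default 0.69, the weight of a `C = 0.5`
  edge).

A synthetic-data module generates ensembles with analytically known
structure — Gaussian ensembles with a prescribed covariance, rigid
two-domain hinge (twist) ensembles, an all-atom contact fixture with
hand-countable side-chain contacts, and planted-community graphs — so that
every stage of the pipeline is validated against an exact or brute-force
oracle.

## Worked example

The bundled demo study is a two-domain hinge ensemble: 30-residue rigid
domains counter-twisting about a single hinge residue (A:31), with small
thermal jitter.

```r
library(psnet)

demo <- demo_dataset(seed = 2, dir = tempfile())
ens  <- read_multimodel_pdb(demo$hinge_pdb)
ens
#> conf_ensemble: 120 frames, 61 atoms, 61 residues (interval: unitless)

# rigidity: the hinge residue tops the force-constant profile
fc <- force_constant_profile(ens)
fc
#> fc_profile: 61 residues, 0 rigid; k range [662, 1.98e+04] kcal/mol/A^2
which.max(fc$value)   # residue index 31 = the hinge

# ensemble contact network (CA toys: 8 A contacts, empirical normalization)
net <- ensemble_network(ens, psn_config(cutoff = 8,
                                        normalization = "empirical",
                                        n_snapshots = 100))
net
#> contact_network: 61 residues, 405 edges, 405 stable (I_min = 3%)

# stable k = 4 communities: one per domain
stable_communities(net, 4)
#> community_set: k = 4, rule either, 2 communities (sizes: 31, 31)
#>   simultaneous-presence fractions: 0.91, 0.94

# correlation-weighted communication graph and betweenness
cm  <- cross_correlation(superpose(ens))
g   <- build_comm_graph(net, cm, c_min = 0)
btw <- betweenness_centrality(g)
btw$key[which.max(btw$value)]   # "A:31" — the bridge carries all
                                # inter-domain shortest paths (b = 0.508)

# optimal route between the domain extremities crosses the hinge
suboptimal_paths(g, "A:1", "A:61", tolerance = 0.01, filter_weak = FALSE)
#> path_ensemble: A:1 -> A:61, 12 path(s) within 0.01 of L_opt = 5.812 (1 optimal)
```

The two planted findings — the hinge residue in the top force-constant
decile and at the top of the betweenness ranking — mirror the
rigidity/centrality correspondence the method is designed to expose:
residues that are mechanically rigid *and* topologically central are the
candidate mediators of allosteric communication.

For real proteins, replace the demo input with a multi-model PDB of your
ensemble and keep the defaults (`cutoff = 4.5`, packaged normalization,
`i_min = 3`, occupancy 0.75); `run_pipeline(pipeline_config(...))` executes
every stage and writes TSV/JSON outputs plus a reproducibility manifest.

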