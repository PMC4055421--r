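---
title: "Ensemble protein structure networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble protein structure networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnet)
```

`psnet` analyzes conformational ensembles of proteins as statistical objects:
it measures which residues are mechanically rigid, how residue motions are
correlated, which side-chain contacts persist across the ensemble, how those
contacts organize into communities, and which residues sit on the shortest
communication routes through the resulting network.  This vignette explains
the models behind each stage, the parameters that matter, and the design
choices made where the methodology leaves room.

## The ensemble model

All analyses start from a `conf_ensemble`: a fixed atom/residue topology plus
an ordered set of coordinate frames, typically read from a multi-model PDB
file with `read_multimodel_pdb()`.  In production use the frames would come
from a molecular-dynamics trajectory; for testing and demonstration they come
from the package's synthetic generators (below).  Residues are keyed by
`(chain, author residue number, insertion code)` and are never renumbered;
hydrogens, waters and (by default) heteroatoms are dropped on read, because
every downstream quantity is defined on amino-acid heavy atoms.

## Force-constant rigidity profiles

For residue $i$, let $d_i(t)$ be the mean distance between its representative
atoms and the atoms of all admissible partner residues in frame $t$.  The
effective force constant is the inverse of the fluctuation of that mean
distance, scaled by thermal energy:

$$k_i = \frac{c\,k_B T}{\langle (d_i - \langle d_i\rangle)^2 \rangle},$$

with $k_B = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, $T = 300$ K and
$c = 3$ by default.  Rigid residues (those whose neighborhood barely moves
relative to them) get large $k_i$; hinge residues between quasi-rigid domains
are the canonical example.  Parameters and conventions:

* **Proportionality constant `factor` (default 3).**  The literature on
  distance-fluctuation force constants is not unanimous about the $3 k_B T$
  versus $k_B T$ convention, and the profile is used comparatively, so the
  constant is an explicit `stability_config()` scalar rather than a
  hard-wired number.  Tests pin the default: a variance of 0.1 A$^2$ gives
  $k = 3 \times 0.5961 / 0.1 = 17.88$ kcal mol$^{-1}$ A$^{-2}$.
* **Neighbor exclusion (default 1).**  Distances to residues $i\pm1$ of the
  same chain are excluded because covalent connectivity makes them nearly
  constant; the exclusion applies in both the alpha-carbon and the all-atom
  representation, and across chains nothing is excluded.
* **Representation.**  `"calpha"` tracks one point per residue; `"allatom"`
  computes a force constant per atom and averages atoms within a residue.
  Both are exposed; alpha-carbon is the default for speed and is what the
  worked examples use.
* **Zero variance.**  A residue with (numerically) zero distance variance is
  reported with a `rigid` flag and `NA` instead of an infinite value;
  plotting caps flagged residues at the profile maximum.

Because $d_i$ depends only on interatomic distances, $k_i$ is exactly
invariant under rigid-body motion of whole frames; the test suite asserts
this to $10^{-9}$ relative and also pins the optimized implementation to a
naive double-loop oracle to ten significant digits.

Computed B-factors use the standard $B_i = (8\pi^2/3)\langle|\Delta
r_i|^2\rangle$ on superposed frames.

## Residue depth

Solvent protection is profiled as residue depth below the solvent-accessible
surface.  The surface is approximated deterministically: each atom carries a
golden-spiral point cloud on its expanded sphere (van der Waals radius plus
the 1.4 A probe), points buried inside any other expanded sphere are
discarded, and an atom's depth is the minimum distance from its center to any
retained surface point.  An isolated atom therefore has depth exactly
$r_{vdw} + r_{probe}$, which the tests assert.  This sphere-point
construction was chosen over water-placement methods because it is
deterministic and dependency-free, and because depth is used comparatively —
`differential_depth()` between two states is the reported quantity.  The
default 96 points per atom is converged to well under 0.1 A on the test
fixtures; doubling it is a one-argument change.

## Superposition, cross-correlations, and modes

Frames are superposed by equal-weight least-squares fitting onto an
iteratively refined mean structure (Kabsch rotations, convergence at
$10^{-6}$ A change in the mean).  No trimming of mobile regions is applied:
the fitting protocol of the source trajectories is unknowable downstream, so
the reproducible equal-weight default is used and documented.

The dynamic cross-correlation matrix uses one representative point per
residue (the alpha carbon):

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\,\langle|\Delta r_j|^2\rangle}} \in [-1, 1],$$

with in-phase motion at $+1$ and anti-phase motion at $-1$.  Zero-fluctuation
residues are flagged and their correlations set to 0.  Principal modes are
the eigenpairs of the $3N$ coordinate covariance; "lowest-frequency modes"
is interpreted as largest-variance principal components (PCA itself has no
frequencies; this is the standard quasi-harmonic correspondence), and the
mobility profile averages the top three modes by default.

## Contact networks and occupancy

Side-chain heavy atoms (glycine falls back to its alpha carbon so every
residue stays a network node) define contacts: $n_{ij}$ counts atom pairs
within 4.5 A, and the interaction strength is the normalized percentage

$$I_{ij} = 100\,\frac{n_{ij}}{\sqrt{N_i N_j}}.$$

Edges require $I_{ij} > I_{min}$ strictly, with $I_{min} = 3\%$ by default —
`imin_scan()` exposes the largest-cluster transition that motivates choosing
$I_{min}$ near the percolation point.  Sequence neighbors within a chain are
never connected; inter-chain pairs always may be.  Decisions worth knowing:

* **Normalization table $N_i$.**  The residue-type contact capacities
  originate in surveys of protein structures whose exact values are not
  reproduced here; the packaged defaults (`default_normalization()`) are a
  documented stand-in proportional to side-chain size, fully overridable,
  and an `"empirical"` mode instead uses the maximum contact count observed
  per residue type in the input — the right choice for non-protein toys such
  as the bundled demo.  No test depends on specific $N_i$ values.
* **Occupancy.**  Over an ensemble, edge occupancy is the fraction of
  evaluated snapshots (deterministic, evenly spaced subsampling to 500 by
  default) in which the edge exists; an edge is dynamically stable when its
  occupancy strictly exceeds 0.75.  Stability is defined edge-wise — the
  reproducible primitive — while community-level persistence is reported
  separately (below), so either reading of "the network remained intact" is
  inspectable.

Hubs are nodes of degree at least 4 on the stable network.

## Clique-percolation communities

A $k$-clique community is the union of $k$-cliques reachable through
adjacent cliques.  Adjacency follows the relaxed rule by default — two
cliques sharing $k-1$ *or* $k-2$ nodes (i.e. at least $k-2$) — with the
strict $k-1$ rule as a switch; results are reported for $k = 3$ and $k = 4$
separately plus their union.  Clique enumeration delegates to igraph's
pivoting traversal with size filtering; the percolation itself, the
stability filtering, and the per-community simultaneous-presence fraction
(how often all member-clique edges coexist in one snapshot) are implemented
here.  Communities are validated against brute-force subset enumeration and
percolation on hundreds of small random graphs.

## Communication graphs, centrality, and paths

Stable contacts are weighted by the correlation between their endpoints,
$w_{ij} = -\ln|C_{ij}|$ (floored at $|C| = 10^{-6}$ so weights stay finite):
strongly correlated contacts are cheap to traverse, uncorrelated ones
expensive.  On this graph:

* **Shortest paths** are computed by Floyd-Warshall with tie-tolerant
  ($10^{-9}$ relative) propagation of minimum-weight path counts $g_{jk}$.
  Hop-count paths (all weights 1) are available as a cross-check by passing
  a unit-weight matrix; the weighted paths are authoritative for every
  reported quantity.
* **Betweenness** is $b_i = \sum_{j<k} g_{jk}(i)/g_{jk}$ normalized by
  $(N-1)(N-2)/2$ (stated in output metadata, since the normalization
  convention varies across the literature); endpoints never count as
  pass-through.  Betweenness runs on the full weighted stable graph — the
  $C_{min}$ filter is *not* applied there, because a weak contact should
  carry (heavily penalized) flow rather than vanish.
* **Path ensembles** between a chosen source and target enumerate all simple
  paths within a length tolerance of the optimum (default 0.69, the weight
  of a $C = 0.5$ edge) by depth-first search with branch-and-bound on a
  Dijkstra lower bound, a hard path cap (default $10^5$) and an overflow
  flag.  Here the correlation filter *does* apply by default: edges with
  $|C| < 0.5$ are excluded, implementing the
  sufficiently-correlated-intermediates criterion at exactly the place it is
  scientifically stated.

All three are validated against exhaustive enumeration on random graphs of
up to 12 nodes, and betweenness additionally against igraph.

## The synthetic-data generators

The generators exist so every stage has an analytic or brute-force oracle:

* `sample_gaussian_ensemble()` draws frames with a prescribed isotropic
  per-node covariance (the scaled pseudo-inverse of a connectivity
  Kirchhoff matrix).  Isotropy is a deliberate simplification: it yields
  closed-form B-factors, correlations and modes with minimal machinery.
  The generator returns the exact covariance it used, so recovery tests
  never re-derive it.
* `make_hinge_ensemble()` builds two internally rigid lattice domains that
  counter-twist about the inter-domain axis, plus optional thermal jitter.
  The twist carries no net rotation or translation; hinge residues lie on
  the axis and move only with the jitter, so they are the rigidity maxima
  by construction, and the single bridge residue carries all inter-domain
  network paths.  Domains are offset from the axis so no domain atom is
  axis-degenerate.  Domains need roughly 20+ residues for their inner
  lattice face to reach the hinge through non-neighbor contacts.
* `make_contact_fixture()` is a six-residue all-atom toy whose side-chain
  contact counts are hand-derived from its documented geometry and shipped
  as a manifest (`inst/extdata/`); the 4.45 A / 4.56 A pair distances
  bracket the 4.5 A cutoff with explicit margins.
* `make_planted_community_graph()` chains complete subgraphs with a known
  overlap, giving exact community oracles.

Randomness is confined to this module and always seeded; every other
function is deterministic given its inputs.

What the generators do **not** emulate: anharmonic and multi-basin dynamics,
solvent and nucleotide chemistry, realistic side-chain packing, and
sequence-dependent contact capacities.  Passing the oracle tests therefore
demonstrates correctness of the implemented estimators and graph algorithms,
not fidelity of any particular biological conclusion drawn from real
trajectories.

## The demo study and what it shows

`demo_dataset()` writes a hinge ensemble (30 residues per domain, 1 hinge
residue, 40-degree maximum twist, 120 frames, 0.05 A jitter) plus a
Gaussian ensemble with its analytic covariance, and a ready pipeline
configuration.  Because the toys are alpha-carbon chains, the demo network
uses an 8 A residue-level contact cutoff and empirical normalization, and
the path-stage correlation filter is disabled: correlations across the
jitter-dominated hinge are legitimately low, which is itself the planted
signature.  The planted outcomes — every hinge residue in the top
force-constant decile, the bridge node at the top of the betweenness
ranking — are recomputed by the test suite and by `scripts/acceptance.R`.
One caveat is stated honestly: with 120 frames the correlation estimates
around the noise-dominated hinge retain sampling noise, and in occasional
realizations a hinge-adjacent gateway residue edges out the bridge node for
the top betweenness slot (the bridge then ranks second or third).

## Numerical choices and degenerate inputs

* Path-length ties: $10^{-9}$ relative tolerance, used consistently by the
  distance recursion, the count propagation and the optimal-path filter.
* Superposition requires three non-collinear selection atoms; collinear
  selections are an error rather than a silent gauge freedom.
* Variances are clamped at zero before inversion; `|C|` is clamped into
  $[0, 1]$ before the logarithm; a correlation magnitude exceeding 1 beyond
  $10^{-8}$ is an error, not a clamp.
* Single-frame ensembles: an error for fluctuation quantities, an explicit
  all-zero profile with a warning for B-factors.
* The run manifest records runtimes and is therefore the only pipeline
  output excluded from the bit-identity guarantee of reruns.

## Problem sizes used in validation

The shipped tests and the acceptance script run Monte-Carlo recoveries at
20,000 frames on 12-node Gaussian models, oracle comparisons on 100 seeded
random graphs of up to 12 nodes, and the full demo study at its default
size; these sizes were chosen so the whole validation suite completes in a
few minutes on one core while keeping every Monte-Carlo bound at least an
order of magnitude away from its threshold.

## Known limitations

* All-atom cross-correlation matrices are not implemented (one
  representative point per residue); neither are current-flow or closeness
  centralities beyond the trivial inverse-mean-distance.
* Binary trajectory formats are not read directly; convert to multi-model
  PDB first (the ensemble contract is format-agnostic, so an adapter can be
  added without touching any analysis code).
* The shortest-path count recursion treats exactly-zero-weight cycles as
  tied paths; with the $10^{-6}$ correlation floor such cycles cannot arise
  from data, only from hand-built graphs.
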