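---
title: "Generating transition-state geometries by equivariant flow matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating transition-state geometries by equivariant flow matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A transition state (TS) is the first-order saddle point connecting reactants
and products on a reaction's potential energy surface; its geometry determines
the activation energy and hence the rate. Quantum-chemical TS searches are
expensive and fragile, so there is real value in a model that proposes 3D TS
geometries directly from the 2D reaction graph — an atom-mapped reaction
SMILES — with no 3D input at all.

`tsflow` treats TS generation as a continuous normalizing flow trained by
optimal-transport conditional flow matching (OT-CFM). A base sample
$x_0 \sim p_0$ (isotropic Gaussian coordinates, or reactant coordinates plus
Gaussian noise) is connected to the reference TS coordinates $x_1$ by the
linear path

$$x_t = (1-t)\,x_0 + t\,x_1, \qquad \dot{x}_t = x_1 - x_0,$$

and a neural vector field $u_\theta(x, t \mid \mathrm{CGR})$ is regressed
onto the constant conditional velocity $x_1 - x_0$. At inference the learned
probability-flow ODE is integrated from $t=0$ to $t=1$ with explicit Euler
steps. Because every metric of interest is rigid-motion aware, the field must
be E(3)-equivariant: rotating or reflecting the input must rotate or reflect
the output, and translations must not matter.

## Reaction conditioning: the CGR

Reactant and product graphs are superimposed into a condensed graph of
reaction (CGR). Every atom and bond carries dual labels — its state before
and after the reaction. Atom features are the element one-hot plus six
graph-perceived properties per side (aromaticity, formal charge,
hybridization, number of bonds, degree, ring membership); bond features are
the dual bond-order categories over {absent, single, double, triple,
aromatic}, so a breaking bond is (single, absent) and a forming bond is
(absent, single). Hybridization is perceived with the standard count
heuristic (any triple bond or two doubles at an atom: sp; any double or
aromatic bond: sp2; otherwise sp3; hydrogen: s), and ring membership is
"incident to a non-bridge edge" on the union graph. All atoms, hydrogens
included, are explicit graph nodes and are ordered everywhere by their
atom-map number — the single row-order convention of the package.

Message-passing edges are the union of all atom pairs within 10 Å in the
*current* flow state and all pairs within 3 bonds in the CGR union graph;
the set is rebuilt from the coordinates at every field evaluation (a config
switch can freeze it), so conditioning follows the geometry as it evolves.

## The equivariant field network

The field network is built at the contract level of modern geometric tensor
networks: invariant scalar features on nodes and edges, steerable features up
to degree $L_{\max}$ (default 2) built from real spherical harmonics of edge
directions, scalar gating, and no Clebsch–Gordan tensor products. Scalars
evolve by pre-LayerNorm message passing; degree-1 channels accumulate
$\sum_j s_{ij}\,\hat r_{ij}$ terms and contribute to the output through a
learned channel mix; degree-2 channels feed back only through their
O(3)-invariant channel norms. Each layer also emits equivariant output
coefficients on the unit and distance-scaled relative edge vectors, and the
per-layer contributions are summed. Sinusoidal embeddings of the flow time
are added to the initial node and edge states, and the raw time values
$(t, 1-t)$ are appended to every layer's MLP inputs.

Two deliberate design choices deserve a note:

* **CoM-frame position injection.** The degree-1 channels are initialized
  from the per-graph centered coordinates. Translation invariance is kept by
  the explicit centering, and rotations/reflections act on positions exactly
  as on any degree-1 feature, so the equivariance contract is unchanged (the
  test suite asserts it numerically to 1e-10). The motivation is practical:
  a field that must transport pure noise onto a structured geometry has to
  infer its global orientation, and giving the first layer direct access to
  the zero-CoM positions shortens that inference.
* **Displacement parameterization.** The network's raw equivariant output is
  interpreted as the *remaining displacement* toward the endpoint, and the
  velocity is $u_\theta = \mathrm{raw}/\max(1-t, \delta)$ with
  $\delta = 0.04$ by default. The raw output then regresses the bounded,
  smooth quantity $(1-t)(x_1 - x_0)$ instead of a field whose conditional
  sharpness diverges as $t \to 1$. The reported CFM loss is unchanged;
  during optimization the residual is taken in displacement space, which
  weights all flow times uniformly (both objectives have the same pointwise
  minimizer — the weighting only redistributes optimization effort across
  $t$).

The forward and reverse passes are implemented as a compiled kernel
(RcppArmadillo) with hand-derived gradients; the test suite checks every
parameter group against central finite differences. Training uses Adam with
global-norm gradient clipping and a warmup-plus-cosine learning-rate
schedule; one training step processes a batch as a single disjoint-union
graph.

## OT pairing, training, and sampling

Before building a training pair, the base sample is centered and rotated
onto the centered TS coordinates by the Kabsch algorithm restricted to
proper rotations (det $+1$); this straightens the transport path and removes
the arbitrary relative orientation of the endpoints. Kabsch degeneracies are
handled by the usual SVD sign correction. Both endpoints live in the
zero-centroid subspace; centroids are unweighted (the package reads "center
of mass" as the geometric centroid since no atomic masses enter anywhere
else; a mass-weighted variant would be a one-line change in `align`).

Per reaction and epoch draw, $t \sim U(0,1)$ and $x_0$ are sampled fresh.
The reactant-noise base adds $\mathcal N(0, 0.25\,\mathrm{I})$ per
coordinate (sd 0.5 Å) to the reactant geometry — the GoFlow-25-R
configuration; the plain Gaussian base is the default.

Sampling integrates the ODE with explicit Euler on the left-endpoint grid
$t_k = k/K$, re-centering the centroid after every step so float drift
cannot leave the zero-CoM subspace. An ensemble of $S$ samples is reduced by
the median-selection rule: compute the coordinate-wise median geometry,
score every sample by its Frobenius distance to that median, and return the
closest sample (ties to the lowest index; even ensembles use the midpoint
median). The ground truth is never consulted. Samples are *not* mutually
aligned before aggregation by default — the coordinate-wise median across
independently oriented samples is itself not rotation-equivariant, so a
config flag (`mutual_align`) optionally Kabsch-aligns all samples onto the
first; the default keeps the literal rule. The presets `goflow-1`,
`goflow-25`, and `goflow-25-r` fix $(S, K)$ = (1, 25), (25, 25), and
(25, 25) with reactant-noise initialization, respectively.

## Metrics

* **D-MAE** — mean absolute difference of all interatomic distances;
  invariant under all rigid motions *and reflections*, so blind to
  chirality errors.
* **RMSD** — after centroid superposition and the optimal *proper* rotation;
  a predicted mirror-image enantiomer scores high by construction.
* **Angle error** — mean absolute angle deviation over all bonded triplets
  of the CGR union graph, in degrees; diatomics return `NA` and are excluded
  from aggregates. Per-reaction means are averaged over the dataset (rather
  than pooling all triplets) — a documented choice where either convention
  is defensible.
* **Steric clash** — repulsion-only Lennard-Jones with
  $\varepsilon = 0.25$ kcal/mol and $\sigma = 0.7$ Å, summed over pairs
  closer than 0.7 Å (no bonded-pair exclusion: only contacts at or below
  the shortest bond lengths in the data register at all). Coincident atoms
  flag as infinite.

## Dataset splits

Three strategies, all 80/10/10 by default: random; reaction-core (reactions
grouped by the canonical key of the dual-labelled subgraph induced on atoms
whose bonding changes — no core ever spans two sets; canonicalization uses
BLISS on a vertex-colored graph with bond labels encoded as colored
subdivision vertices, so map renumberings of the same transformation
collide); and barrier-height (the top and bottom decile of barrier heights
are pooled and halved between validation and test, leaving train as the
contiguous inner band). Hydrogens are part of the core by default —
hydrogen-transfer templates hinge on them.

## The synthetic fixture generator

Tests and desk-scale runs use generated toy reactions: 3–7 heavy atoms from
{C, N, O} plus explicit hydrogens, a random tree scaffold, and one
bond edit drawn from a 14-template library (break/form of C–C/C–O/C–N and
X–H bonds, hydrogen transfers, a double-to-single order change). Reactions
sharing a template share a reaction core, cluster sizes are deliberately
singleton-heavy (at least two thirds of templates hold one reaction), and
barrier heights are lognormal (median 30 kcal/mol, sdlog 0.4). "TS"
geometries are laid out by distance-geometry-style optimization: bonded
pairs pulled to element-pair reference lengths (forming/breaking bonds
stretched by 1.25), non-bonded pairs pushed beyond 1.6 Å, with a
minimum-distance guarantee of 0.8 Å — every ground-truth fixture is
steric-clash-free under the default clash parameters, which keeps clash
regressions sharp.

These fixtures are distribution targets for the generative machinery, **not**
physical saddle points: passing tests demonstrate the correctness of the
transport, aggregation, metric, and splitting machinery, not chemical
accuracy on real reactions. Real TS data (e.g. the RDB7 set: 11,926
gas-phase H/C/N/O reactions of up to seven heavy atoms) plugs in through the
same CSV + XYZ loader.

## Problem sizes and numerical choices

Desk-scale runs in the test suite and the acceptance script use width-64
networks (3 layers, $L_{\max}=2$, 32 radial basis functions), fixture sets
of 1–200 reactions, and a few thousand Adam steps; the full-size default
(width 256, ~5M parameters) matches the published configuration axis but is
not trained in the tests. Tolerances: equivariance is asserted to 1e-4
(observed ~1e-15); Kabsch optimality against a random-rotation oracle to
1e-9; geometry round-trips to 1e-6 Å. Degenerate inputs: coincident atoms
give infinite clash; diatomics have undefined angle error; collinear point
sets take the SVD sign-correction branch in Kabsch; `t` outside $[0,1]$ and
non-finite coordinates are rejected at the field boundary.

## Known limitations

* At desk scale the flow underfits the early (noise-dominated) part of the
  transport: inferring the orientation of the target structure from nearly
  pure noise is the expressivity bottleneck of a small equivariant network,
  and trajectories that drift off the training envelope see a weak field.
  Mid- and late-time conditional accuracy is much higher. Consequently
  single-reaction memorization to crystallographic accuracy needs far more
  optimization than a few CPU-minutes allow; the package is faithful to the
  method, not a shortcut around its training cost.
* Coordinate-wise median aggregation across unaligned samples mixes
  orientations; distance-based metrics are unaffected, but the aggregate
  "median geometry" itself is not a meaningful structure unless
  `mutual_align = TRUE`.
* The SMILES dialect is the fully atom-mapped bracket-atom subset that
  atom-mapped reaction datasets use; stereo descriptors are parsed and
  ignored, and aromatic perception is taken from the input rather than
  recomputed.
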