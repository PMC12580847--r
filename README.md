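# tsflow

Transition-state (TS) geometries — the first-order saddle points that set a
reaction's activation energy — are expensive to obtain quantum-chemically.
`tsflow` generates 3D TS geometries for single-step reactions directly from
the atom-mapped 2D reaction graph ("reactant>>product" SMILES with every
atom mapped), with no 3D input, for computational and synthetic chemists who
need TS guess structures at high throughput.

## Method

The reaction is encoded as a **condensed graph of reaction** (CGR): reactant
and product graphs superimposed, every atom and bond carrying dual
before/after labels. Conditioned on the CGR, a time-dependent
**E(3)-equivariant vector field** $u_\theta(x, t)$ is trained by
**optimal-transport conditional flow matching**: a base sample
$x_0 \sim \mathcal N(0, I)$ (or reactant coordinates + noise,
$\sigma^2 = 0.25$) is centered and Kabsch-aligned (proper rotations only)
onto the centered reference TS $x_1$, the pair is interpolated linearly,

$$x_t = (1-t)\,x_0 + t\,x_1,$$

and the network is regressed onto the constant conditional velocity
$x_1 - x_0$. Sampling integrates the probability-flow ODE with explicit
Euler steps from $t=0$ to $t=1$; an ensemble of $S$ samples is reduced by
**median selection** (return the sample closest, in Frobenius norm, to the
coordinate-wise median geometry — the ground truth is never consulted).
Geometries are scored by distance-matrix MAE (D-MAE), Kabsch RMSD (proper
rotations, so enantiomer errors score high), bond-angle error, and a
repulsion-only Lennard-Jones **steric-clash** score
($\varepsilon = 0.25$ kcal/mol, $\sigma = 0.7$ Å, 0.7 Å cutoff). Dataset
splits: random, reaction-core (template-disjoint), and barrier-height
(inner 80% trains, the decile tails go to validation/test), all 80/10/10.

The field network follows the geometric-tensor-network contract: invariant
node/edge scalars, steerable features up to degree 2 built from spherical
harmonics of edge directions, scalar gating, no Clebsch–Gordan tensor
products; edges join atoms within 10 Å of each other in the current flow
state or within 3 bonds in the CGR. The forward/backward kernel is compiled
(RcppArmadillo). See the methods vignette
(`vignettes/tsflow-methods.Rmd`) for the model, its assumptions, and design
choices.

## Worked example

Everything below runs in a few minutes on one CPU; the fixture generator
builds toy reactions with known clash-free TS geometries, so no download is
needed.

```r
library(tsflow)

reactions <- make_fixture_dataset(fixture_spec(n_reactions = 12, seed = 42,
                                               n_cores = 4))
reactions[[1]]
#> <ts_reaction fx0001: 18 atoms, 17/16 bonds (R/P), TS geometry, barrier 41.1 kcal/mol>

net <- field_net(width = 32, n_layers = 2, seed = 1)
net
#> <field_net: width 32, 2 layers, L_max 2, 38,039 parameters>

fit <- train(reactions, net,
             train_config(epochs = 8, batch_size = 4, lr = 5e-3, seed = 1,
                          n_draws = 2, clip_norm = 5))
round(fit$loss_curve, 3)
#> [1] 8.513 1.802 1.388 1.284 0.999 1.243 1.508 0.896

ens <- generate(fit$net, reactions[[1]], n_samples = 25, n_steps = 25, seed = 7)
ens
#> <sample_ensemble: 25 samples, selected #19 (d = 7.3428)>

d_mae(ens$final, reactions[[1]]$ts_geometry)
#> [1] 0.803559
steric_clash(ens$final)
#> [1] 123.9967
```

The loss is the training objective (mean squared residual of the predicted
transport, per atom); `d_mae` is the mean absolute error over all
interatomic distances in Å against the reference TS, and `steric_clash` the
repulsive LJ score in kcal/mol — an 8-epoch toy model is still far from
converged, which these numbers show honestly. Template-disjoint splitting:

```r
s <- split_by_core(reactions, seed = 3)
s
#> <split_assignment (core, seed 3): 0 train / 2 val / 10 test>
```

(with 12 reactions over 4 templates, one 9-member template dominates and the
greedy core assignment lands it in the test set — no template ever spans two
sets).

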