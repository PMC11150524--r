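---
title: "Methods: ferrohydrodynamic channel flow and boosted velocity surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ferrohydrodynamic channel flow and boosted velocity surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Magnetically guided drug nanocarriers are steered through the blood stream by
an external permanent magnet. Assessing such a delivery system needs the
velocity field of the carrier-laden blood in the vessel, which is classically
obtained by CFD — accurate but too slow to embed in design loops. `ferroflow`
implements the two-stage hybrid approach: a ferrohydrodynamic channel-flow
simulation generates a velocity dataset of rows $(x, y, U)$, and a boosted
regression ensemble learns the map $(x, y) \mapsto U$ as a fast surrogate.

## Stage 1: the flow model

### Governing equations

The blood is treated as an incompressible Newtonian fluid (defaults
$\rho = 1050\ \mathrm{kg/m^3}$, $\mu = 3.5\times10^{-3}\ \mathrm{Pa\,s}$ —
standard whole-blood values) in a 2D plane channel:

$$\rho\, \mathbf{U}\cdot\nabla\mathbf{U}
  = \nabla\cdot\mu\left(\nabla\mathbf{U} + (\nabla\mathbf{U})^T\right)
  - \nabla p + \mathbf{F}, \qquad \nabla\cdot\mathbf{U} = 0 .$$

The domain is the rectangle $x \in [-0.14, 0.08]$, $y \in [-0.02, -0.01]$ m
(a 1 mm gap, walls at $y = -0.02$ and $-0.01$), matching the extents of the
reference dataset. Although a vessel is tubular, the reference data are a 2D
$(x, y)$ field, so a plane channel with the mid-gap at $y = -0.015$ is the
geometry that reproduces them.

The inlet carries the Poiseuille profile modulated by a heartbeat factor,

$$u(y, t) = u_\mathrm{peak}\left(1 - \left(\tfrac{y - y_c}{h}\right)^2\right)
            \left(1 + a\sin(2\pi f t)\right),$$

and the run is a steady snapshot at one phase of the beat (default: the
systolic peak of a 72 bpm cycle, $a = 0.02$). The centreline velocity at that
phase is set to $0.500050$ m/s, the maximum of the reference dataset.
Walls are no-slip; the outlet is a zero-gradient, mass-conserving boundary.

### The magnetic body force

The magnet is modelled as a point dipole placed outside the channel (default
2.5 mm below the lower wall), with field

$$\mathbf{H}(\mathbf{r}) =
  \frac{3(\mathbf{m}\cdot\hat{\mathbf{r}})\hat{\mathbf{r}} - \mathbf{m}}
       {4\pi |\mathbf{r}|^3},$$

and the dilute linearly magnetizable suspension experiences the Kelvin body
force $\mathbf{F} = \mu_0 \chi (\mathbf{H}\cdot\nabla)\mathbf{H}$
(default $\chi = 0.05$). The dipole is a deliberate, configurable stand-in:
the original magnet/vessel geometry behind the reference dataset is not
publicly specified, so a closed-form field that is testable (inverse-cube
decay, mirror symmetry) is used instead, with all parameters in the
`magnet:` config block.

One property of this model deserves emphasis. Outside its source a dipole
field is curl-free, and for constant $\chi$

$$\mu_0\chi(\mathbf{H}\cdot\nabla)\mathbf{H}
  = \nabla\!\left(\tfrac{1}{2}\mu_0\chi |\mathbf{H}|^2\right),$$

a pure gradient. In incompressible flow a gradient body force is absorbed
into the pressure and leaves the velocity unchanged — the classical result
that a uniform ferrofluid in a current-free field feels magnetic *pressure*,
not magnetic *stirring*. The simulated velocity field is therefore
Poiseuille-dominated, with only a discretization-level residue near the
magnet (observed at about 0.1% of the centreline velocity, independent of
the dipole moment). Velocity perturbations would require spatial gradients
of susceptibility (a carrier concentration field) or a rotational external
field; both are out of scope, and the exported dataset statistics are
consistent with this: the reference mean velocity is reproduced by the
parabolic profile alone.

### Discretization

The solver is a staggered (MAC) finite-volume scheme advanced in pseudo-time
by Chorin projection to a steady state:

- first-order upwind convection, centred diffusion;
- wall cells use *quadratic* ghost extrapolation (fitting a parabola through
  the two nearest cell values and the zero wall value), so that the discrete
  Poiseuille solution is an exact fixed point of the scheme — a mirror ghost
  leaves an $O(1)$ wall error in the second derivative and a 0.2% profile
  bias;
- each step projects onto the divergence-free space with a direct sparse
  Cholesky solve of the pressure-correction Poisson equation (Neumann at
  walls/inlet, Dirichlet at the outlet face), giving discrete divergence at
  round-off ($\sim 10^{-14}\ \mathrm{s^{-1}}$, contract $10^{-6}$);
- the state is initialized from the analytic Poiseuille solution and its
  linear pressure, so a force-free run converges immediately and the default
  run settles in a few hundred steps;
- convergence is declared when $\max |\partial u/\partial t|$ falls below
  `steady_tol` (default $5\times10^{-4}\ \mathrm{m/s^2}$, about 0.1% of the
  inertial scale $u_\mathrm{peak}^2/L$); exceeding the iteration cap is an
  error reporting the final residual. Channel Reynolds numbers above 2000
  (turbulence onset) are refused — the default run sits at $\mathrm{Re}
  \approx 150$ based on the gap.

The 425 × 41 default grid (17,425 nodes, ~10× finer spacing along the vessel
axis than across the gap in physical units) exceeds the ≥ 17,000 rows of the
reference dataset. The exported `U` is the velocity magnitude
$\sqrt{u^2 + v^2}$; for this flow the transverse component is negligible, so
magnitude versus axial component is immaterial, but the choice is recorded
here.

## Stage 2: preprocessing

- **Isolation forest** (100 trees, subsample 256, score threshold 0.6,
  seeded) with the standard path-length score
  $s(x) = 2^{-E[h(x)]/c(\psi)}$, $c(n) = 2H(n-1) - 2(n-1)/n$. On gridded CFD
  data the flagged rows are mostly domain-border nodes (about 5% of rows at
  the default threshold); the screen exists to catch genuinely anomalous
  rows and is kept deterministic and configurable.
- **80/20 split** by a seeded uniform permutation (first $\lfloor 0.8
  n\rfloor$ rows to train).
- **Min–max scaling** of inputs and target, fitted on the training split
  only and applied to the test split — fitting on all rows would leak test
  information into the model scale. Metrics are computed after inverse
  transformation, on the raw m/s scale; this is forced by the consistency
  identity $\mathrm{RMSE} \approx \mathrm{sd}(y)\sqrt{1 - R^2}$ holding for
  the reference metric values on the raw scale.

## Stage 3: the surrogates

Three base families, each wrapped in AdaBoost.R2:

- **CART regression trees** (variance-reduction splitting, depth cap 8,
  leaf minimum 1, grown by `rpart` with pruning disabled). Classification
  impurities (entropy, Gini) do not apply to a continuous target, so
  variance reduction is the splitting criterion.
- **K-nearest neighbours** ($K = 2$, true Euclidean distance; ranking is
  unchanged by the square root, exact ties break to the lowest training-row
  index).
- **Multilayer perceptron** (hidden layers (66, 29), ReLU, linear output,
  mini-batch Adam on MSE, seeded He initialization; defaults 60 epochs,
  batch 512, learning rate $2\times10^{-3}$).

**AdaBoost.R2** (linear loss): round $t$ fits a base model on the weighted
sample (trees take weights natively; KNN/MLP fit a weighted bootstrap
resample), computes $l_i = |\hat y_i - y_i| / \max_j |\hat y_j - y_j|$,
$\bar L_t = \sum_i w_i l_i$, confidence $\beta_t = \bar L_t / (1 - \bar
L_t)$, and reweights $w_i \leftarrow w_i \beta_t^{1 - l_i}$ (renormalized).
Rounds with $\bar L_t \ge 1/2$ are discarded and stop the sequence; an
essentially perfect round ($\bar L_t < 10^{-12}$) is kept with a capped
confidence weight. Predictions combine with weights $\ln(1/\beta_t)$; both
weighted-average (the default, following the study's description) and
weighted-median aggregation are implemented and config-selectable.

Ensemble sizes follow the tuned values: 450 (tree), 10 (KNN); the MLP
ensemble runs 20 estimators (the tuned value was 180) — the staged-score
curve shows accuracy saturating within a handful of estimators on this
dataset, and 20 keeps a full run at desk scale.

## Hyperparameter tuning: the bat algorithm

`bat_step()` implements exactly the three printed update equations
($f_i = f_\min + (f_\max - f_\min)\beta$;
$v_i \leftarrow v_i + (\Theta_i - \Theta_\ast) f_i$;
$\Theta_i \leftarrow \Theta_i + v_i$, then clipping and integer rounding).
Analysing the one-bat linear map shows these three equations alone are
divergent (both eigenvalues exceed 1 in modulus), so bats spiral outward and
pin at the bounds: in a 20-bat, 50-iteration sphere-function experiment the
bare variant reached the optimum in 0/10 seeds. The tuner therefore enables
the canonical echolocation mechanics — a loudness-gated local random walk
around the best-known position with an increasing pulse rate — by default
(10/10 seeds in the same experiment); `local_search = FALSE` exposes the raw
dynamics for study. The fitness is seeded k-fold cross-validated $R^2$
(default 3 folds); fitting failures return a $-\infty$ sentinel so the swarm
steps over degenerate candidates (an exactly constant target makes $R^2$
undefined and lands in this path). Mixed integer/tuple dimensions (e.g.
hidden layer sizes) are handled by continuous relaxation, rounding and
flattening. Acceptance-level runs use the tuned hyperparameters as a frozen
preset rather than re-tuning, so results do not depend on a stochastic
search.

## Diagnostics

`staged_scores()` gives the $R^2$-versus-estimator-count curve;
`learning_curve()` reports train/CV $R^2$ versus training size (fold-wise
seeded subsets; default sizes 500/2000/8000 under 3-fold CV);
`partial_dependence()` averages predictions over a background sample with
one input pinned to a grid (the full pipeline uses a seeded 1000-row
background subsample and one batched prediction call, which keeps the
450-tree ensemble tractable); `prediction_surface()` evaluates the surrogate
on a tensor grid inside the training domain, with negative velocities
clipped to the physical floor of zero. Plot rendering is deliberately out of
scope — the package computes the arrays.

## What the generated data do and do not exercise

The simulator emulates the deposited dataset's structure and statistics: a
steady, laminar, Newtonian, single-phase 2D field on a uniform lattice with
a parabolic transverse profile. Passing surrogate metrics on these data
shows the learners reproduce a smooth, essentially one-dimensional velocity
field with high fidelity; it does not exercise non-Newtonian rheology,
elastic walls, transient cardiac sweeps, particle-laden two-phase effects,
or concentration-gradient magnetic stirring, and surrogate accuracy on such
flows cannot be inferred from these tests. The uniform node lattice also
yields a slightly different velocity standard deviation than the reference
dataset's (non-uniform) node placement, which is why the dataset sd is not a
reproduction target.

## Numerical choices and edge cases

- All randomness flows from one global seed through fixed per-stage
  offsets; every stage is individually reproducible.
- Min–max scaling refuses constant columns (naming them); the split refuses
  empty sides; the solver refuses grids under 3 nodes per axis, body forces
  on mismatched grids, and non-finite fields.
- Ties in CART splits resolve to the first best split in rpart's scan
  order; KNN ties to the lowest row index; the weighted median takes the
  smallest prediction reaching half the cumulative weight.
- Problem sizes in the shipped tests are chosen for desk-scale runs: the
  full default-preset study executes once and is shared across
  acceptance-level checks; unit tests use coarse grids (e.g. 61 × 17) where
  the same contracts hold.

## Known limitations

- The dipole + constant-$\chi$ Kelvin force cannot alter the incompressible
  velocity field (see above); magnetic effects show up in the pressure.
- First-order upwinding smears sharp transverse gradients of any *applied*
  rotational force; the default flow has none.
- The isolation-forest border effect means a fraction of near-wall rows is
  excluded from training; wall behaviour of the surrogate is still anchored
  by the remaining rows.
- The MLP's loss is non-convex; determinism is per-seed, not
  per-architecture.
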