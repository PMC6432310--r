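---
title: "Simulating lipid-membrane phase separation on a dynamically triangulated Finsler-geometry surface"
author: "fgmem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating lipid-membrane phase separation on a dynamically triangulated Finsler-geometry surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmem)
```

## The model

Ternary lipid membranes (DOPC / DPPC / cholesterol) phase-separate into
liquid-ordered (Lo, DPPC/cholesterol-rich) and liquid-disordered (Ld,
DOPC-rich) domains, and the domain pattern — two circular patches, a
stripe, many small rafts, or a bud pinched off through a narrow neck —
changes with composition and mechanical parameters.  `fgmem` simulates a
coarse-grained model of this process: a closed, dynamically triangulated
fluid surface whose **triangles** each carry a binary phase label
$\sigma = +1$ (Lo) or $-1$ (Ld).  The Hamiltonian is

$$S(\mathbf r, \sigma) \;=\; \lambda S_0 + S_1 + \kappa S_2, \qquad
S_0 = \sum_{ij} (1 - \sigma_i \sigma_j), \quad
S_1 = \sum_{ij} \gamma_{ij}\,\ell_{ij}^2, \quad
S_2 = \sum_{ij} \kappa_{ij}\,(1 - \mathbf n_i \cdot \mathbf n_j),$$

where the sums run over bonds (edges), $\ell_{ij}$ is the bond length,
$\mathbf n_i, \mathbf n_j$ are the unit normals of the two triangles
sharing the bond, and $\sigma_i, \sigma_j$ are their labels.  $k_BT = 1$
throughout.

* $S_0$ is an Ising-like **aggregation energy**: it is non-zero only on
  (Lo,Ld) bonds, so $S_0 = 2\times$(number of domain-boundary bonds) and
  $\lambda S_0$ is precisely a discrete line-tension energy.  This
  identification — line tension emerging from a microscopic
  label-interaction — is the conceptual point of the model.
* $S_1$ and $S_2$ are the Gaussian (tension) and bending energies of the
  Helfrich–Polyakov surface model, but with **phase-dependent
  coefficients** derived from a Finsler metric: each triangle carries a
  metric factor $\rho = c$ (Lo) or $1$ (Ld), and

  $$\gamma_{ij} = \kappa_{ij} = \tfrac14\!\left(\rho_i + \rho_i^{-1} +
  \rho_j + \rho_j^{-1}\right) =
  \begin{cases}
  (c + c^{-1})/2 & \text{(Lo,Lo)}\\
  (2 + c + c^{-1})/4 & \text{(Lo,Ld)}\\
  1 & \text{(Ld,Ld).}
  \end{cases}$$

  At $c = 8.37$ these are $4.24$, $2.62$ and $1$; at $c = 5$ they are
  $2.6$, $1.8$ and $1$ — so the Lo phase is several times stiffer than
  Ld, in line with experimental estimates of the Lo/Ld bending-rigidity
  ratio.  The formula is symmetric under $c \leftrightarrow 1/c$, so
  `modelParams()` canonicalizes $c \ge 1$.

Two variants are provided.  **Model 2** is the full model above.
**Model 1** keeps $\kappa_{ij}$ but fixes $\gamma_{ij} = 1$, the
canonical Gaussian energy; then bond lengths (and triangle areas) are
statistically uniform across phases and the Lo fraction $\phi_0$ equals
the Lo *area* fraction.  In model 2 the larger Lo tension shrinks Lo
triangles, so the area fraction falls below $\phi_0$ — at $c = 1$ the two
variants are identical (and reduce to the standard fluid-surface model),
which the tests assert energy-for-energy.

## Sampling

The surface is a subdivided icosahedron (`buildIcosphere()`): subdivision
frequency $\ell$ gives $N = 10\ell^2 + 2$ vertices, $N_T = 2N - 4$
triangles, $N_B = 3N - 6$ bonds; $\ell = 24$ reproduces the production
lattice $N = 5762$ of the full-scale study.  Two Metropolis moves act at
$k_BT = 1$:

* **Vertex moves**: a uniformly chosen vertex is displaced by a vector
  uniform in a ball of radius $R$; acceptance $\min(1, e^{-\delta S})$.
  $R$ is tuned multiplicatively toward $50\%$ acceptance during
  thermalization (`tuneRadius()`), then frozen, so the measurement phase
  satisfies detailed balance with fixed parameters.
* **Bond flips**: the shared diagonal of two adjacent triangles is
  replaced by the opposite diagonal, making the surface fluid — vertices
  *and* triangles (hence domains) diffuse.  Labels obey the conserving
  rule: two equal labels stay; two different labels are redistributed at
  random over the two new triangles.  The Lo count $N_{To} = \phi_0 N_T$
  is therefore invariant, matching experiments at fixed composition.
  Flips that would create a duplicate bond, drop a vertex below
  coordination 3, or act on a pair of triangles sharing two bonds are
  rejected outright; these guards are the standard ones for
  sphere-topology dynamical triangulation.

A sweep is $N$ vertex-move attempts plus $N$ flip attempts, randomly
interleaved (the move ordering is not otherwise constrained), after which
the surface is recentred at the origin — the energy is translation
invariant, so recentring fixes the centre of mass without biasing any
observable.

Energy differences are computed **locally and exactly**: a vertex move
touches only the bonds of its star triangles, a flip only the flipped
diagonal plus the four quadrilateral boundary bonds.  The running energy
is accumulated incrementally in double precision and audited against a
full recomputation every `recomputeInterval` sweeps (default $10^4$); the
run reports the maximum observed drift (typically $<10^{-12}$ relative).
A proposed move that would create a zero-area triangle gets
$\delta S = +\infty$ and is rejected, since its normal is undefined.

### The strongest correctness check

The partition function is invariant under the global rescaling
$\mathbf r \to \alpha\mathbf r$, under which $S_1 \to \alpha^2 S_1$ while
$S_0, S_2$ are unchanged.  Differentiating at $\alpha = 1$ gives the
exact identity
$$\langle S_1 \rangle / N = \tfrac{3(N-1)}{2N} \;\xrightarrow{N\to\infty}\; \tfrac32$$
for *every* parameter set (the $-3$ counts the translational zero modes
pinned by recentring).  Because it holds conditionally on any
triangulation and label configuration, it probes the vertex-move sampler
end to end.  The test suite verifies it to $<1\%$ in a fast-relaxing
configuration and probes it at the $\pm 0.02$ level on the subdivision-4
lattice for both model variants.  A caveat worth knowing: at stiff
parameters ($\kappa\,\kappa_{ij}$ up to $\sim 40$) the surface's shape
and breathing modes have correlation times of $10^4$–$10^5$ sweeps, so a
single $2\times 10^5$-sweep production average of $S_1/N$ carries
slow-mode noise of roughly $\pm 0.035$ — consecutive windows of that
length in one long run range over about $1.43$–$1.53$ around the exact
value, even though the long-run mean converges to it.  Tight
verification of the identity therefore needs either soft-bending
parameters or runs an order of magnitude longer.

## Parameters and defaults

| parameter | meaning | typical values | units |
|---|---|---|---|
| $\lambda$ | aggregation / line-tension coupling | $0.03 \le \lambda \le 3$; mixing below $\lambda \approx 0.1$, separation above | $k_BT$ per bond |
| $\kappa$ | global bending rigidity | $7$–$20$ | $1/k_BT$ |
| $c$ | Finsler metric ratio Lo : Ld | $5$, $8.37$ | — |
| $\phi_0$ | Lo triangle fraction (conserved) | $0.3$–$0.9$ | — |
| $R$ | vertex-move radius | auto-tuned to $50\%$ acceptance | length |

Choices the problem leaves open, decided here once:

* **Lattice**: icosahedral subdivision, the construction consistent with
  the production size $5762 = 10\cdot 24^2 + 2$.  $N_{To}$ is
  `round(phi0 * NT)`, a rounding convention for compositions that do not
  divide $N_T$ exactly.
* **Initial state**: random labels at $\phi_0$ (the two-phase coexistence
  configuration) on a sphere whose radius is immaterial by scale
  invariance.  The default radius sets the mean bond length to the
  equilibrium value implied by the identity above,
  $\langle \gamma \ell^2\rangle = 1.5\,N/N_B$ with the random-mixing
  average of $\gamma_{ij}$ (`equilibriumEdgeLength()`); starting at the
  equilibrium scale removes the slow relaxation of the global breathing
  mode, whose autocorrelation otherwise dominates thermalization.
* **Schedule**: thermalization/measurement split is configuration-driven,
  defaulting to 25% / 75% when only a total is given.  Tuning windows of
  100 sweeps with per-step factors clamped to $[0.5, 1.5]$ keep the
  radius controller stable.
* **Observable definitions**: the diameters $D_1 \ge D_2 \ge D_3$ are
  full extents (max minus min vertex projection) along the principal axes
  of the gyration tensor — extents match the "diameter" reading of the
  shape-anisotropy diagnostics, and $D_2$ discriminates prolate/stripe
  ($D_1 > D_2 \simeq D_3$) from oblate/two-circular
  ($D_1 \simeq D_2 > D_3$) shapes.  Twice-RMS eigenvalue surrogates would
  change absolute values but not these signatures.

## Morphology classification

Published phase diagrams for this class of model label configurations by
visual inspection of snapshots.  `classifyMorphology()` operationalizes
the labels as a pure function of domain-component statistics
(`domainComponents()`, connected components of equal-label bond-sharing
triangles): one/two circular domains, stripe (one Lo band, two Ld caps),
3–6 comparable patches as a multi-circular raft, and many small
components as the unseparated random state.  The cutoffs are explicit
configurable constants (`morphologyThresholds()`) — they are a
convention, not a claim.  **Budding** is reported as a *candidate* flag
only: a large Lo component whose total boundary length is well below the
circumference of the equal-area disc (default ratio $0.7$) has the
geometry of a bud behind a narrow neck.  Since the model has no
self-avoidance, budded surfaces may self-intersect; the flag reports
geometric evidence, not a verified topology change.

## What the simulations show at reduced scale

The full-scale study ($N = 5762$, $10^8$-sweep runs) maps phase diagrams
in the $(\lambda, \phi_0)$ and $(\kappa, \phi_0)$ planes.  The package's
tests reproduce the *structure* of those diagrams on reduced lattices
(subdivision 3–8, $10^4$–$5\times 10^5$ sweeps, sizes chosen so the whole
suite runs on a desktop):

* $\lambda$ far below the mixing threshold leaves the boundary-bond
  fraction at the random-mixing value $2\phi_0(1-\phi_0)$ with no
  coarsening trend;
* $\lambda$ well above it coarsens the Lo set into a few connected
  components with a boundary well below random mixing.  The property
  tests use $\lambda = 0.8$ for the separated side: the label sector is
  an Ising model with coupling $\lambda$ on the 3-regular
  triangle-adjacency graph, whose critical coupling is $\approx 0.66$
  (honeycomb value), and the geometric contribution of the
  $\kappa_{ij}/\gamma_{ij}$ mismatch to the boundary free energy is
  small — so robust separation on a reduced lattice needs $\lambda$
  clearly above that threshold, noticeably higher than the separation
  onset reported for the full-scale system;
* model 2 at $c = 8.37$ shows the strong Lo-triangle shrinkage (area
  fraction clearly below $\phi_0$) while model 1 does not.

These reduced runs demonstrate the mechanisms, not the quantitative phase
boundaries: locations of first-order boundaries, the stable one-circular
region, and budding statistics require the full-scale runs, which the
engine supports but the test suite does not attempt.  What passing tests
show about real membranes is correspondingly limited: the model is a
two-label coarse-graining with no self-avoidance, no spontaneous
curvature, no area/volume constraints and no hydrodynamics, so it speaks
to equilibrium domain morphology, not kinetics.

## Numerical notes

* Incremental $\delta S$ vs full recomputation agrees to $10^{-9}$
  relative (tested on randomized meshes); the periodic full recompute
  caps accumulation drift.
* Normals come from the consistent outward winding maintained by the
  flip bookkeeping, keeping $1 - \mathbf n_i\cdot\mathbf n_j \in [0,2]$
  stable; windings are validated (each directed edge traversed exactly
  once) on construction and audited during flip stress tests.
* All randomness flows through R's RNG, including inside the compiled
  sweep loop, so a single `set.seed` (or the `seed` argument of
  `runSimulation()` / `runScan()`) makes runs bit-reproducible;
  checkpoints store the RNG state so resumed runs continue the identical
  stream.
* Degenerate inputs: zero-area triangles abort energy evaluation with a
  diagnostic; moves that would create one are auto-rejected.

## A short run

```{r example, eval = FALSE}
params <- modelParams(
  lambda = 0.4, kappa = 7, c = 5, phi0 = 0.3,
  variant = "model1", subdivision = 6
)
run <- runSimulation(params, runSchedule(totalSweeps = 2e4), seed = 1)
run$meanS1PerN # ~ 1.5 by scale invariance
comp <- domainComponents(run$surface)
classifyMorphology(comp, surface = run$surface)$label
semiAxes(run$surface)
writeSnapshot(run$surface, "membrane.ply") # view in any mesh viewer
```

Phase-plane scans (`runScan()`) run one seeded, independent simulation
per grid point and emit the TSV phase table from which a diagram is
drawn; the command-line driver in `inst/cli/fgmem.R` wraps both entry
points for shell use.
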