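---
title: "Simulating sprouting angiogenesis with structural adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sprouting angiogenesis with structural adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioadapt)
```

## The model

`angioadapt` simulates how a sparse seed network of microvessels in a thin
(20 um) sheet of tissue grows into a stable, hierarchical, space-filling
microvascular network. Six coupled mechanisms act on a daily time step:

1. **Network hemodynamics.** The vessel network is a graph of straight
   segments. Each segment has Poiseuille resistance
   $R = 128\,\eta_{app} L / (\pi D^4)$, with the apparent viscosity
   $\eta_{app}(D, H_D)$ given by the empirical in-vivo law for blood in
   microvessels (the Fahraeus-Lindqvist relation with the wall-layer
   correction). Setting the net flow at every interior node to zero gives
   a sparse linear system for nodal pressures. Red cells partition
   unevenly at diverging bifurcations (an empirical logit law in the
   fractional blood flow, daughter diameters and parent hematocrit), so
   hematocrits, viscosities and flows are iterated to a joint fixed
   point. Wall shear stress is $\tau_w = \Delta P \, D / (4L)$.

2. **Oxygen transport.** The steady tissue PO2 field solves
   $D_{O_2}\alpha \nabla^2 P = M(P)$ with Michaelis-Menten consumption
   $M(P) = M_0 P/(P_0 + P)$ ($P_0$ = 1 mmHg), by a two-dimensional
   Green's-function method: vessel elements (<= 10 um) are oxygen line
   sources, tissue points on a 50 um grid are sinks, and the free-space
   logarithmic kernel (per unit slab thickness) superposes their fields,
   plus a uniform constant fixed by requiring total source strength to
   balance total sink strength. Intravascular PO2 is marched along each
   flow pathway by conservation of the convective flux
   $f = Q\,(H_D C_0 S(P_b) + \alpha_{eff} P_b)$ with the Hill saturation
   $S(P) = P^n/(P^n + P_{50}^n)$ ($n = 3$, $P_{50} = 38$ mmHg), and an
   intravascular (blood-to-wall) transport resistance parameterized by a
   diameter-dependent Nusselt number.

3. **VEGF field.** Hypoxic tissue releases growth factor at a rate that
   rises from the basal $M_{G0}$ in well-oxygenated tissue to $6 M_{G0}$
   in anoxia. The concentration solves the modified Helmholtz problem
   $D_G \nabla^2 C - K_G C + M_G(P) = 0$ with zero flux at the tissue
   boundary; exchange with vessels is neglected. The diffusion length
   $\sqrt{D_G/K_G}$ is 200 um, and attainable steady concentrations span
   $M_{G0}/K_G \approx 0.7$ pM to $6 M_{G0}/K_G \approx 4.2$ pM.

4. **Sprouting.** Each day, one point is sampled uniformly on every
   segment; a sprout forms there with probability
   $k_p\,\frac{(C - C_{th})_+}{(C - C_{th})_+ + C_{th50}}\,L\,\Delta t$
   (capped at 1), i.e. zero below the threshold $C_{th} = 0.8$ pM and
   saturating at the maximal rate $k_p = 2\ \mathrm{mm^{-1} day^{-1}}$.
   Sprouts start perpendicular to the parent (sign fair), keep a 10 um
   diameter while non-flowing, and elongate 50 um/day in 5 um substeps.
   The direction is perturbed daily by a Gaussian angle (variance 0.1
   rad^2) and pulled toward vessels sensed by filopodia within a sector
   of radius 100 um and half-angle pi/3, with weights
   $(1 - r/R_{max})(1 - |\theta|/\theta_{max})$ vanishing at the sector
   edge. Growth is deliberately *not* biased up the VEGF gradient. A tip
   passing within 5 um of another vessel connects to it; a tip crossing
   the tissue boundary, or a connection landing on a network boundary
   node, suppresses the sprout.

5. **Structural adaptation and pruning.** Flowing, non-fixed segments
   change diameter by $\Delta D = D\,S_{tot}\,\Delta t / T$
   ($T = 4.5$ day), with
   $S_{tot} = \log_{10}(\tau_w + \tau_{ref})
   - k_p \log_{10} \tau_e(P) + k_m S_m + k_c S_c - (k_s + \epsilon)$.
   Here $\tau_e(P) = 100 - 86 e^{-5000 (\log_{10}\log_{10} P)^{5.4}}$ is
   the empirical shear-pressure set point; the local metabolic signal
   $J_m = (1 - P_{O_2}/P_{O_2,ref})_+^N$ (with $N = 2$ for adequate
   low-PO2 sensitivity) is convected downstream in proportion to
   $J_m l_{seg}$, giving the saturating
   $S_m = \log_{10}(1 + \hat J/(Q + Q_{ref}))$; each segment feeds
   $S_m l_{seg}$ into a conducted response that travels upstream along
   vessel walls decaying as $e^{-s/L_c}$ ($L_c$ = 17.3 mm), summing where
   conducted streams merge and dividing equally where conduction splits,
   with $S_c = J_c/(J_c + J_{01})$; and $\epsilon$ is a fresh
   $N(0, 0.1)$ draw per segment per day on the shrinking tendency
   $k_s = 2.549$. Segments whose diameter falls strictly below the 3 um
   red-cell passage minimum are pruned, together with every segment that
   can no longer lie on a path between two boundary nodes (its flow
   necessarily ceases), computed from the block-cut tree of the flowing
   subgraph.

6. **Tension-induced migration.** Vessels carry longitudinal tension
   proportional to diameter. The normalized resultant at a node is
   $\mathbf f_t = \sum D_i \mathbf e_i / \sum D_i$; nodes with
   $|\mathbf f_t| > \lambda_t = 0.05$ migrate along it at speed
   $v_{max}(|\mathbf f_t| - \lambda_t)/(1 - \lambda_t)$
   ($v_{max}$ = 1 um/day), displacements applied synchronously and capped
   so no segment drops below 10 um and no node leaves the tissue. This
   relaxes the initial 90/90/180-degree bifurcations toward a smooth
   distribution near 120 degrees; with migration disabled the branching
   angles stay peaked at 90 and 180 degrees.

The daily step runs: flow, oxygen, VEGF, sprout formation, elongation and
connection, adaptation and pruning, then migration, so fields always
reflect the structure at the start of the day and adaptation uses the
same day's hemodynamics.

## Seed network and study conditions

The seed "skeleton" emulates a mesenteric preparation: a rectangular
4.23 mm^2 sheet bounded by two fixed-diameter venules that converge on a
single outflow (pressure 15 mmHg), fed by two arterioles. One arteriole
is held at 59.09 mmHg with inflow hematocrit 0.3742; the other supplies a
fixed 15 nl/min; both deliver blood at PO2 75 mmHg. Each bounding venule
carries 28.1 nl/min inflow at hematocrit 0.4 and PO2 38 mmHg. Exactly
five boundary nodes carry these conditions. Oxygen demand is uniform,
0.5-2.5 cm^3 O2/(100 cm^3 min) (default 2). Because the observed
network's exact geometry is not numerically published, the generator
reproduces the topology class and the printed boundary data, not
coordinates; initial calibers (arterioles tapering 25 to 12 um, venules
35 to 20 um, capillaries 8 um) are configurable defaults chosen as
typical mesenteric values. The inflow hematocrit of the flow-controlled
arteriole is not printed and defaults to that of the pressure-controlled
one.

## Numerical choices

* **Flow fixed point:** relative tolerance 1e-4 on flows and hematocrits,
  at most 100 outer iterations, hematocrit updates damped by 0.5; a final
  consistent pass re-solves pressures at the converged viscosities.
  Junctions of more than three vessels resolve phase separation pairwise
  in descending-flow order; converging junctions mix by red-cell flux
  conservation.
* **Oxygen solver:** the vessel-source, tissue-sink and balance equations
  are linearized jointly each iteration (the Michaelis-Menten sink about
  the current field) and solved as one system by a Schur complement on
  the tissue block, with tissue PO2 projected non-negative, Newton steps
  capped at 60 mmHg, and the blood-PO2 march under-relaxed by 0.5.
  Convergence is declared below 0.1 mmHg; sub-mmHg residual bounces on
  degenerate near-zero-flow segments are tolerated. Segments carrying
  less than 1e-3 nl/min are treated as passive (no source elements), and
  marched blood PO2 is capped at the highest inflow PO2. Vessel elements
  are at most 10 um long; near-pair kernels use analytic line averages
  and self-interactions the line average at the vessel surface.
* **VEGF solver:** direct sparse solve of the 5-point discretization on
  the 50 um tissue grid with mirrored (zero-flux) boundary stencils.
  A free-space Bessel-kernel superposition serves as its cross-check in
  the test suite.
* **Sprout bookkeeping:** daily growth adds one straight segment (5 um
  increments merged, so no segment is shorter than 10 um); connections
  extend the trailing segment to the intercept node rather than creating
  a sub-minimum connector; intercepts are shifted along the target, or
  snapped to its end node, to respect the minimum length. A merged
  non-flowing web of sprout material becomes flow-eligible only once it
  anchors to the flowing network at two or more nodes, since only then
  can a pressure difference drive flow through it. Degenerate
  anastomoses that would duplicate an existing edge between the same two
  nodes are suppressed; coincident parallel edges would make the oxygen
  source system singular.
* **Determinism:** all stochastic draws come from named substreams
  (sprouting, growth direction, adaptation noise, fixture jitter) derived
  from one master seed, so disabling one mechanism does not shift the
  draws seen by the others, and a trajectory is a pure function of
  (config, seed).

## What the generator emulates, and what it does not

The synthetic skeleton honors the printed boundary conditions, domain
area, thickness and topology class (bounding venular loop, two feeding
arterioles, five boundary nodes), but not the exact observed geometry;
quantities that depend on the particular observed layout (e.g. the
observed network's 30.2 mm total length) are context, not targets, for
simulations started from it. Tissue demand is uniform; real mesentery
has fat islands and heterogeneous consumption. The model is strictly
two-dimensional, excludes intussusceptive (splitting) angiogenesis and
gradient-following sprout growth, and treats all vessel types alike for
sprouting and connection. Passing tests on the synthetic skeleton
therefore demonstrate the mechanisms and their interactions, not a
digitized reproduction of one biological specimen.

## Scales used by the test suite

Full-scale runs (4.23 mm^2, 200 days, six seeds) reproduce the published
network-level statistics but take hours. The package's own test suite
exercises the same mechanisms at reduced scale, as its standing choice of
problem size: unit and oracle fixtures use 0.25 mm^2 domains with 10 x 10
tissue grids; mechanism-contrast simulations (shunt suppression,
migration on/off branching angles, sprout-rate comparison, adaptation
knockout) run on roughly 0.5-1 mm^2 domains for 30-60 days. The
finite-difference oxygen oracle uses a 6.25 um grid padded far beyond the
tissue (approximating the free-space kernel), a numerically calibrated
lattice Green's function to translate grid values at deposited line
sources into continuum wall values, and the same intravascular marching
as the main solver.

## Known limitations

* The oxygen fixed point can retain a sub-mmHg residual oscillation when
  remodeling produces nearly-degenerate, almost-unperfused loops; the
  affected segments carry negligible oxygen and the global balance still
  closes to well under 2%.
* The free-space-plus-constant treatment of the tissue boundary in the
  oxygen solver approximates the closed-sheet (no-flux) condition; the
  VEGF solver imposes zero flux exactly.
* Unconnected sprout material is never retired (no removal rule is
  defined for it), so transient non-flowing length can exceed what a
  rule with sprout regression would give.
* With near-saturated Michaelis-Menten consumption the absolute tissue
  PO2 level is loosely pinned (a 1% change in delivered oxygen moves the
  level by several mmHg), which is why the oracle comparisons are run at
  capillary-scale flows where extraction pins the level robustly.
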