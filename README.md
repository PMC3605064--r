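# angioadapt

Microvascular networks face two conflicting design requirements: a dense,
mesh-like structure keeps every tissue cell within the short diffusion
range of oxygen, while a hierarchical, tree-like structure delivers blood
over long distances at low resistance. `angioadapt` simulates how real
microvascular beds reconcile the two — by **over-abundant stochastic
sprouting** in response to a growth factor released by hypoxic tissue,
followed by **refinement through structural adaptation and pruning** —
in a thin two-dimensional tissue sheet modeled on rat mesentery.

It is intended for researchers in microcirculation and vascular biology
who want a mechanistic sandbox: every mechanism (sprouting, filopodia
homing, diameter adaptation, conducted responses, tension-induced
migration, pruning) can be toggled or re-parameterized to ask what each
contributes to the emergent network.

## The model in brief

Each simulated day the package solves, on the current network:

* **blood flow** — nodal-pressure solve with the empirical in-vivo
  apparent-viscosity law η(D, H_D) and red-cell phase separation at
  bifurcations; wall shear stress τ_w = ΔP·D/(4L);
* **oxygen** — a 2-D Green's-function source/sink method for the coupled
  intravascular/tissue PO2 field, with Hill-saturation convection
  (P50 = 38 mmHg, n = 3) and Michaelis–Menten consumption
  M = M0·P/(P0 + P);
* **VEGF** — a reaction–diffusion field D_G∇²C − K_G·C + M_G(PO2) = 0
  with hypoxia-dependent release (basal to 6× basal) and diffusion
  length √(D_G/K_G) = 200 µm;

then grows sprouts where VEGF exceeds the 0.8 pM threshold (50 µm/day,
persistent direction, filopodia attraction within 100 µm), connects tips
that reach other vessels, adapts every flowing diameter by
ΔD = D·S_tot·Δt/T from shear, pressure, metabolic and upstream-conducted
stimuli, prunes vessels below the 3 µm red-cell minimum (with cascade
removal of dead pathways), and lets unbalanced wall tension migrate
nodes, smoothing branch angles toward 120°.

## Worked example

```r
library(angioadapt)

# seed skeleton: 4.23 mm^2 sheet, five boundary nodes, demand 2
net <- generate_skeleton(skeleton_spec(), seed = 1)
net
#> vascular_network: 22 nodes (5 boundary), 22 segments, 0 non-flowing (sprout) segments
#> total vessel length 10.96 mm

flow <- solve_flow(net)
oxy  <- solve_oxygen(net, flow)
oxy
#> oxygen_state: 1702 tissue points, mean PO2 10.8 mmHg, hypoxic fraction 50.29%
veg <- solve_vegf(oxy, net$domain)
veg
#> vegf_state: 1702 points, C_G 2.00-3.88 pM, 100.0% above threshold
```

Half the tissue of the bare skeleton is hypoxic (PO2 < 1 mmHg), so VEGF
is everywhere above the sprouting threshold: the seed condition that
drives angiogenesis. A simulation then grows and refines the network:

```r
cfg <- simulation_config(days = 40, seed = 7)
res <- simulate_angiogenesis(net, cfg)
tail(res$records[, c("day", "total_length_mm", "flowing_length_mm",
                     "hypoxic_fraction_pct")], 3)
```

`res$records` holds one row per day (lengths, inflow, mean PO2, hypoxic
fraction, sprout/pruning counts); `summarize_network()` computes the
network-level statistics (total length, mean tissue-to-vessel distance,
flow rate, PO2 distributions, branching-angle histogram) and
`replicate_stats()` aggregates them across seeds. Networks and fields
can be written as delimited exchange tables, CSV grids and legacy VTK
(`write_network()`, `write_vtk_network()`, `write_vtk_grid()`).
A command-line wrapper for generate/run/metrics lives in
`inst/scripts/angioadapt.R`.

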