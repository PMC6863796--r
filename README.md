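# stentsim

In-stent restenosis — the re-narrowing of a stented coronary artery by
neointimal tissue — is driven by smooth muscle cells (SMCs) that switch to a
proliferative *synthetic* phenotype after the stent injures the vessel wall,
divide, and secrete loose proteoglycan-rich extracellular matrix (ECM), until
a recovering endothelium and sufficient wall shear stress (WSS) arrest them.
`stentsim` is a desk-scale 3D multiscale simulator of this process for
researchers in computational vascular physiology: it couples an off-lattice
agent-based model of the arterial wall to a lattice-Boltzmann blood-flow
solver, and provides the histomorphometry-style metrics (per-strut neointimal
thickness, signed and relative neointimal area) used to compare simulated
cross-sections with histology.

## Model

* **Wall mechanics.** SMCs, internal/external elastic lamina (IEL/EEL)
  covered SMCs, ECM blobs and stent material are elastic spheres connected
  by springs: linear contact repulsion, linear attraction up to a cutoff of
  1.3× the rest distance. Same-lamina pairs attract with twice the plain
  stiffness, so a ruptured lamina retracts and sheds strain. The wall is
  kept in mechanical equilibrium by overdamped variable-step 4th-order
  Runge–Kutta relaxation (`dx/dt = F/γ` until `max|F| <` tolerance).
* **Geometry.** Vessels are straight cylinders or toroidal segments
  (centreline a planar arc, 28 mm curvature radius at full scale). In curved
  segments every agent's rest radius is scaled by the local metric factor
  `(R_curv + h)/R_curv`, so the bent packing is built in equilibrium.
  Parametric multi-ring stents (or any watertight STL/OBJ/PLY surface,
  filled with 30 µm agents) are deployed by quasi-static radial expansion at
  a 1.4:1 oversizing; lamina agents whose lamina-bond strain exceeds the
  rupture threshold become plain SMCs (vessel injury).
* **Flow and WSS.** The agent geometry is voxelized; steady flow is solved
  with a D3Q19 BGK lattice-Boltzmann method (interpolated bounce-back walls,
  Poiseuille inlet, zero-gradient outlet) and WSS is mapped back to
  lumen-facing agents.
* **Biology (1 h steps).** Lumen-exposed SMCs turn synthetic and cycle
  (30 h); they arrest permanently where the endothelium is functional and
  WSS > 0.27 Pa; contact inhibition pauses the cycle; divisions conserve
  volume. Strained synthetic SMCs (>10 % bond strain) and their daughters
  emit ECM blobs with probability P = 0.1 per hour, placed abluminally —
  on average 3 blobs per cell cycle, i.e. 60 % of new tissue is loose ECM.
  Endothelium recovery is uniform and stochastic per lumen site.

## Worked example

```r
library(stentsim)

cfg <- make_scenario("curved-stented-28d", scale = 0.25, seed = 11,
                     agent_scale = 1.43)
dep <- deploy_scenario(cfg)          # build vessel, deploy stent, injure wall
dep$report
#> <deployment_report> peak strain 0.3 | 143 IEL ruptures, 12 EEL ruptures, 1410 wall-strut contacts

res <- simulate_scenario(cfg, flow_interval = 24L)   # 28 days of growth
tail(res$state$series[, c("time_h", "n_smc", "n_ecm", "coverage")], 1)
#>     time_h n_smc n_ecm coverage
#> 672    672  7535  3482        1

sec <- extract_section(res$state, position = 0.75)   # histology-style slice
sec
#> <section_metrics> s = 0.75 mm, 6 struts, lumen area 0.2256 mm^2
ni_area(sec)$relative
#> [1] 0.546275
```

The deployment report counts lamina ruptures (the model's vessel-injury
state); the growth series tracks SMC/ECM agent counts and endothelial
coverage — growth stalls as coverage approaches 1 and WSS rises; the
section metrics mirror what a histologist would measure on the matching
slide (strut landmarks lettered A… clockwise from the epicardial side),
here a relative neointimal area of 55 % in this mid-stent slice of a
deliberately small, coarse-grained run.

## Command line

`exec/stentsim` wraps the package for shell use:

```sh
stentsim fixture --name curved-stented-28d --scale 0.5 --seed 1 --out fx/
stentsim deploy  --config fx/curved-stented-28d.yaml --out deployed.rds
stentsim grow    --config fx/curved-stented-28d.yaml --state deployed.rds --days 28 --seed 17 --out run/
stentsim metrics --state run/final.rds --position 3.0 --out sec
```

See `vignettes/multiscale-restenosis.Rmd` for the full account of the model,
its parameters and the design decisions.
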