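---
title: "A multiscale agent-based model of in-stent restenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale agent-based model of in-stent restenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stentsim)
```

`stentsim` simulates neointimal growth in a stented coronary segment by
coupling four sub-models in an hourly loop: agent-based wall mechanics,
lattice-Boltzmann hemodynamics, a biological ruleset for smooth muscle
cells (SMCs) and extracellular matrix (ECM), and an implicit endothelium.
This vignette is the package's own account of the science: the model and
its assumptions, the parameters that matter, what the synthetic scenarios
do and do not emulate, and the numerical choices behind the implementation.

## The multiscale loop

After a stent is deployed into the vessel wall, each simulated hour runs:

1. **Voxelize** the agent geometry (wall, ECM, stent) onto a regular grid.
2. **Solve steady flow** with a D3Q19 BGK lattice-Boltzmann method and
   compute wall shear stress (WSS) at the lumen surface.
3. **Map WSS** back onto lumen-facing agents.
4. **Biology**: endothelium recovery, growth/division with arrest, ECM
   production.
5. **Re-equilibrate** the wall mechanics.

The biological step sets the pace (1 h); flow and mechanics are treated as
quasi-static between steps. `run_growth()` may refresh the flow solution
every `flow_interval` hours instead of every hour — geometry changes by
much less than a voxel per hour — and always re-solves when any agent has
moved more than half a voxel; `force_flow = TRUE` restores strict
once-per-hour solves.

## Wall mechanics

Agents are elastic spheres joined by springs. For centre distance $d$ and
rest distance $s = r_i + r_j$ the central force is piecewise linear:
repulsion $k_{rep}(s-d)$ under overlap; attraction $-k_{att}(d-s)$ up to
strain $(c{-}1)/2$; then a linear ramp to zero at the cutoff $c\,s$
(default $c = 1.3$). The ramp keeps the force continuous, so the overdamped
relaxation descends a well-defined potential. Beyond the cutoff, bonds
detach — stretched tissue tears rather than stretching indefinitely, which
is what lets an oversized deployment injure the wall plastically.

Two special rules: pairs covered by the *same* elastic lamina (both
IEL-covered or both EEL-covered) attract twice as strongly, representing
the lamina's tensile strength; stent material interacts by contact
repulsion only (metal does not adhere to tissue). The doubled lamina
attraction is what makes a ruptured lamina retract: when an IEL-covered
agent is converted to a plain SMC its neighbours lose the doubled bond and
pull back, shedding strain — and exposing medial SMCs to the lumen.

Time integration is an overdamped (inertialess) classical RK4 on
$\dot x = F/\gamma$ with a variable step: the step is capped so no agent
moves more than `max_disp` (4 µm) per step and so the stiffest contact
mode stays inside the RK4 stability region; steps that increase the
maximum force are rejected and retried smaller. Relaxation stops when the
maximum net force on a mobile agent falls below `force_tol`, or when it
stops improving (a handful of frustrated contacts can pin the maximum; the
residual is then carried into the next hour — the tissue is quasi-static,
not exactly stationary). Stiffness magnitudes are calibration knobs, not
measured quantities; the defaults ($k_{att}/k_{rep} = 0.3$) let a strut
indent the wall without numerical blow-up.

Vessel ends are held in their end cross-section planes (free to slide
in-plane). This emulates the continuation of the artery beyond the
segment without locking packing misfit into the boundary rows.

## Vessel construction and curvature

Vessels are concentric shells of agents around a straight or toroidal
centreline: rings with staggered axial rows (hexagonal-like packing), one
shell per wall layer, innermost IEL-covered and outermost EEL-covered with
plain medial SMC shells between. For curved segments every rest radius is
multiplied by the local metric factor $(R_{curv}+h)/R_{curv}$ (with $h$
the signed offset toward the outer curve), ring spacing follows the same
factor and shell radii are marched with it, so circumferential, radial and
axial gaps all match the scaled rest distances to first order in
$\rho/R_{curv}$. The residual second-order misfit is removed by a short
in-build equilibration; the returned wall satisfies the equilibrium
tolerance as built, and the scaling demonstrably reduces the construction
misfit compared with uniform radii. Without the scaling a bent packing
carries systematic axial strain — outer-curve bonds stretched, inner-curve
compressed — which would contaminate the strain-gated biology.

The toroidal curvature radius is 28 mm at full scale (mid-range for a
porcine right coronary artery) and scales geometrically with the vessel.

## Stent deployment and vessel injury

Parametric stents are slotted-tube-like: rings of short axial bars equally
spaced around the circumference (alternating half-pitch offsets), filled
with agents representing 30 µm cubes of stent material. Deployed stents in
curved vessels carry no residual curvature — stents are straighter than
the vessel, so deployment locally straightens the segment, which is what
loads the inner (myocardial) curve. Deployment maps the stent radially
inward to a crimped state and expands it linearly over 20 quasi-static
steps (bounded relaxation after each, full equilibration at the end).

Lamina rupture is driven by the stretch of the lamina itself: the maximum
bond strain *between same-lamina agents*. IEL-covered agents whose peak
lamina strain exceeds 0.20 become plain SMCs; the EEL threshold is 0.28,
just below the bond-detachment strain of 0.30, so it breaks only in the
most extreme cases. These thresholds are declared assumptions: the elastin
rupture strain is a calibration input, and any value at or above the
detachment strain would be unreachable by construction. With the 1.4:1
oversizing used in the scenarios (the balloon-to-artery ratio that induces
restenosis in healthy porcine vessels), ruptures concentrate near struts
in straight vessels and shift toward the inner curve in toroidal ones,
where the metric-scaled rest radii make the same deployment produce
systematically larger strain.

## Hemodynamics

Blood is Newtonian (µ = 3.5 mPa·s, ρ = 1050 kg/m³), flow is steady per
biological step. The solver is D3Q19 BGK with Bouzidi (linear
interpolated) bounce-back using sub-voxel wall distances computed from the
agent spheres, a parabolic velocity profile at the inlet and a
zero-gradient outlet rescaled to unit density (which anchors the pressure;
the steady offset of the interior mean density from 1 is the physical
pressure drop, and the divergence guard watches the *change* of mean
density between convergence checks instead). Unit mapping picks the time
step for a peak lattice velocity of about 0.08 while keeping the BGK
relaxation time in (0.5, 2).

WSS is evaluated at wall-adjacent fluid cells as the largest-magnitude
eigenvalue of the deviatoric non-equilibrium stress tensor — exact for
locally simple shear and independent of the staircase-quantised wall
normal. Because bounce-back pollutes the non-equilibrium moments *at*
boundary cells, the stress is sampled one and two cells into the fluid
along the normal and linearly extrapolated to the wall, then averaged over
the local wall surface. On a straight tube this reproduces the Poiseuille
wall shear to ~2 % with sub-percent scatter; the closed-form checks in the
test suite pin this down.

Two scale choices matter at desk scale. First, the volumetric inlet flow
is fixed at its initial value, so WSS rises as the lumen narrows — the
negative feedback that saturates growth. The default inlet velocity gives
mid-physiological WSS (~1.5 Pa) in the unstented tube, so the 0.27 Pa
arrest threshold is meaningfully exercised. Second, in a scaled-down
vessel Reynolds number and WSS cannot both match physiology; growth runs
preserve WSS, while the curvature-asymmetry analysis preserves Re (~100)
and prepends an analytic entrance tube (`voxelize(..., entrance = )`) so
the Dean flow can develop before the stented segment, as one does for
bent-tube hemodynamics (at entrance lengths much shorter than
$\sim 0.06\,\mathrm{Re}\,D$ the asymmetry has not formed and can even
transiently reverse).

## Biology

All rules run on 1 h steps:

* **Phenotype.** SMCs exposed to the lumen immediately post-stenting —
  medial cells bared by IEL rupture — switch to the synthetic phenotype.
  An SMC at the surface still counts as covered if an intact IEL-covered
  agent lies within contact range (rasterisation can expose sub-voxel
  chinks of an intact lamina).
* **Growth and arrest.** Synthetic SMCs advance a 30 h cycle clock unless
  contact-inhibited (pair overlap above 15 % of rest distance) or
  arrested. Arrest is evaluated per lumen site: functional endothelium
  *and* WSS > 0.27 Pa arrests permanently (the cell reverts to
  contractile and remains quiescent even if WSS later falls). The
  nitric-oxide pathway is folded into this binary endothelium flag. Cells
  completing the cycle divide into two volume-conserving daughters along
  a random, tangentially biased axis; growing cells swell as
  $r_0 (1 + t/T)^{1/3}$, so each completed cycle adds one cell volume.
* **ECM.** Synthetic SMCs above 10 % bond strain (and their daughters)
  become producers; each producer emits one ECM blob — the volume of a
  contractile SMC, same mechanical rules — with probability P = 0.1 per
  hour, placed abluminally along the outward centreline ray with a small
  tangential jitter (the abstraction of chemotactic SMC migration toward
  the lumen). Production stops at arrest. The stochastic rule avoids
  stepwise growth; over a 30 h cycle it yields on average 3 blobs per
  cell, hence a loose-ECM fraction of newly formed tissue of
  $PT/(PT+2) = 0.6$.
* **Endothelium.** Recovery is uniform and stochastic over a fixed
  angular × axial grid of lumen sites, each denuded site recovering with
  probability 0.009 per hour (≈90 % coverage by day 10, near-complete in
  the third week — the re-endothelialisation time scale of healthy porcine
  coronaries); coverage never reverts. The whole segment is denuded at
  deployment.

A single R RNG stream drives all stochastic rules, so a (config, seed)
pair fully determines the trajectory, and checkpoints store the RNG state
so a restored run continues bit-identically.

## Cross-section metrics

`extract_section()` cuts the vessel with a plane normal to the centreline,
projects agents within a 60 µm slab (histology section scale), and traces
the lumen contour from a slab-projected occupancy mask with a
morphological closing at half the agent radius — a plane through packed
spheres cuts disconnected discs, and the closing restores the contiguous
tissue profile. Strut landmarks are cluster centroids of stent agents in
the slab, lettered clockwise from the epicardial (outer-curve) 12 o'clock.

Per-strut neointimal thickness is measured from the strut centre along the
ray toward the lumen centroid to the first tissue-boundary crossing, minus
the strut half-thickness; a bare strut therefore reads ~0. The neointimal
area is the area of the polygon through the strut centres minus the total
lumen area — lumen lying outside the polygon subtracts, so the NI area can
be negative; no clipping is applied. Relative NI area divides by the strut
polygon area. Note that with few struts the chord geometry alone makes the
polygon smaller than a circumscribed lumen, so the relative NI area of a
freshly stented section is not exactly zero even for a perfect circular
lumen; comparisons between time points, or against histology measured the
same way, are unaffected. Externally traced contours (CSV polylines) can
be fed through `section_from_contours()` so in vivo sections are measured
by the same code path.

## Synthetic scenarios and what they show

`make_scenario()` generates fully deterministic study inputs: a rigid tube
for the flow oracle, straight/curved stented twins differing only in
vessel curvature, and an analytic phantom section with closed-form
metrics. `scale` multiplies the vessel dimensions (desk scale 1 = 1.25 mm
lumen radius, 6 mm segment; the stent spans ~70 % of the segment at every
scale); `agent_scale` coarsens the agents; the wall shell count follows
`scale/agent_scale` so the geometry stays similar and the agent count
scales with the cube of `scale`. Two resolution constraints matter when
shrinking the system. First, the cell-to-lumen size ratio must stay below
roughly 0.07, or the tissue added per division is so large relative to
the lumen that growth outruns endothelial recovery and occludes the
vessel — a resolution artefact. Second, resolving the inner-curve injury
of a straightening stent requires the straightening displacement
(stent half-span squared over twice the curvature radius) to span at
least a couple of agent diameters. The test suite therefore runs the
growth scenarios at scale 0.25 with 21 µm agents (~7,000 agents, about
fifteen minutes for a 28-day run on one CPU) and the deployment/flow
asymmetry analyses at scale 0.5 with 19.5 µm agents. The model rules are
identical at every scale, but reduced resolution coarsens strain
localisation and makes per-section quantities noisy — passing tests
demonstrate the mechanisms (inner-curve injury, myocardial low WSS,
strut-focal vs diffuse ECM, growth saturation), not quantitative
agreement with any particular vessel. The stochastic ECM composition
(60 % loose ECM, 3 blobs per cycle) is resolution-independent and is
checked at its stated tolerance.

The generator does not emulate: patient- or animal-specific centrelines,
plaque, non-planar curvature, pulsatile or non-Newtonian flow, balloon
mechanics (dogboning, scratching), drug elution, or cyclic-strain biology.

## Numerical choices and limitations

* Equilibrium tolerance 5e-4 (≈0.5 µm displacement equivalent); growth
  runs use 1.5e-3 with a bounded per-hour step budget, carrying the
  residual into the next hour. The relaxation keeps a Verlet pair list
  with a 20 µm skin, rebuilt on drift.
* Voxelization marks voxels whose centre lies inside any agent sphere,
  with an effective radius floor of 0.62 voxel edges and a one-voxel
  morphological closing so stretched tissue cannot leak; the flow domain
  is clipped a margin inside the open tube ends so every lattice plane
  cuts a closed wall annulus.
* The lumen-facing classification, WSS mapping and endothelium sites all
  live on the voxel/site resolution; sub-voxel features are not resolved.
* Degenerate inputs: coincident agent centres get a capped deterministic
  fallback force; sections with no struts return empty landmark sets; NI
  area requires at least three struts; non-watertight meshes and
  self-intersecting tori are rejected with diagnostics.
* The wall has no bending stiffness and no transmural pressure, so tissue
  sags inward between struts more than a pressurised artery would; this
  shows up as a nonzero baseline relative NI area immediately
  post-deployment.
* One simulated trajectory per (config, seed); stochastic variation across
  seeds is small relative to means at the tested sizes but grows as the
  agent count shrinks.
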