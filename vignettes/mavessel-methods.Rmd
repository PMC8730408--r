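---
title: "Models and methods: particle-based blood flow in microaneurysm channels"
author: "mavessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`mavessel` simulates red blood cells (RBCs) and platelets flowing through a
retinal capillary that carries a saccular microaneurysm (MA), and reduces
the resulting cell tracks to two transport statistics associated with
thrombus formation inside MAs: the probability that a platelet passing the
channel migrates into the MA lumen, and its residence time inside. This
vignette documents the models, the parameters that matter, the numerical
choices, and the limits of what the desk-scale fixtures can show.

## Blood plasma: dissipative particle dynamics

Plasma is a DPD fluid: particles interact pairwise within a cutoff $r_c$
through the conservative/dissipative/random triplet

$$
\mathbf F^C_{ij} = a_{ij}\,(1 - r/r_c)\,\hat{\mathbf r}_{ij}, \qquad
\mathbf F^D_{ij} = -\gamma\, w_R(r)^2 (\hat{\mathbf r}_{ij} \cdot
\mathbf v_{ij})\,\hat{\mathbf r}_{ij}, \qquad
\mathbf F^R_{ij} = \sigma\, w_R(r)\, \theta_{ij}\,
\hat{\mathbf r}_{ij}/\sqrt{\Delta t},
$$

with $w_R(r) = (1 - r/r_c)^s$ and the fluctuation–dissipation constraint
$\sigma^2 = 2\gamma k_BT$ enforced by construction. Defaults follow common
soft-matter practice for cell suspensions: $a = 25$, $\gamma = 4.5$,
$k_BT = 1$, $r_c = 1$, solvent number density $\rho = 3$, and a softened
random-force exponent $s = 1/4$, which raises the fluid viscosity relative
to the linear weight at the same $\gamma$. The conservative weight is kept
linear. $\theta_{ij}$ is a symmetric uniform variate of unit variance drawn
once per pair per step — a standard, cheaper alternative to Gaussian noise
with identical hydrodynamics. All of these are configuration parameters.

Integration uses the modified velocity-Verlet scheme with intermediate
velocity weight $\lambda = 1/2$: positions advance with the current forces,
forces are re-evaluated at the predicted velocities, and the velocity
update averages old and new forces. With velocity-independent forces the
scheme reduces to plain velocity Verlet and conserves energy to
$\mathcal O(\Delta t^2)$; the pairwise antisymmetry of all nonbonded forces
conserves linear momentum to floating-point accumulation error, which the
test suite checks directly.

## Units

Model units are anchored by three scales (`unit_system()`): one model
length is 1 μm, the energy unit is $k_BT$ at 310 K, and the mass unit is
$10^{-15}$ kg, roughly the plasma mass of 1 μm³. The derived time unit is
$t = \ell\sqrt{m/\epsilon} \approx 0.48$ ms. This anchoring maps the
physiological capillary velocities (0.25–2 mm/s) to 0.12–0.97 in model
units — at or below the unit thermal velocity — so geometry can be typed in
micrometres while the fluid stays in its quasi-incompressible regime.
Matching the transport coefficients of real plasma is *not* attempted; the
fluid viscosity is only required to be self-consistent, and the no-slip
validation compares profile shapes, not absolute magnitudes.

## Cell membranes

A cell is a closed triangulated network of $N_v$ vertices carrying the free
energy

$$ V_t = V_s + V_b + V_a + V_v , $$

where

* $V_s$ — per-edge worm-like-chain attraction plus a power-law repulsion
  $k_p/l^{m}$ ($m = 2$), in equilibrium at the built edge length $l_0$ with
  maximum extension $l_m = l_0/x_0$, $x_0 = 0.45$;
* $V_b$ — dihedral bending energy $k_b\,[1 - \cos(\theta - \theta_0)]$ with
  $k_b = 2k_0/\sqrt3$, the standard triangulated-sheet correspondence to a
  continuum bending rigidity $k_0$;
* $V_a, V_v$ — quadratic global area and volume penalties
  $k_a (A - A_0)^2/2A_0$ and $k_v (V - V_0)^2/2V_0$, plus a per-triangle
  local-area term with coefficient $k_d$.

Every force routine is the analytic negative gradient of its energy; the
suite verifies each term against central finite differences to better than
$10^{-4}$ relative error — the module's master oracle.

**Presets.** The normal RBC uses $N_v = 500$, shear modulus
$\mu_0 = 4.73$ μN/m, bending rigidity $k_0 = 2.4\times10^{-19}$ J,
reference area 132.9 μm² and volume 92.5 μm³ (surface-to-volume ratio 1.44,
reduced volume 0.64). The diabetic preset stiffens the shear modulus
5-fold. The platelet is an oblate spheroid with $N_v = 48$, aspect ratio
0.38 and volume 6 μm³, with both moduli 100× the normal RBC so it behaves
as a rigid body.

**Calibration.** Bond coefficients come from the closed-form small-strain
shear modulus of a WLC-plus-repulsion triangulated network,

$$
\mu_0 = \frac{\sqrt3\,k_BT}{4 p l_m x_0}\left(\frac{x_0}{2(1-x_0)^3}
- \frac{1}{4(1-x_0)^2} + \frac14\right)
+ \frac{\sqrt3\,(m+1)\,k_p}{4\,l_0^{m+1}},
$$

solved for the persistence length $p$ with $k_p$ fixed by per-edge force
balance at $l_0$. The round trip through this relation reproduces the
target to machine precision.

**Mesh construction.** Arbitrary exact vertex counts (500 and 48 are not
icosphere subdivision counts) are achieved by spreading points on the unit
sphere (Fibonacci lattice + pairwise-repulsion relaxation), triangulating
by convex hull, and mapping the sphere onto the target shape. The map onto
surfaces of revolution (oblate, biconcave) matches cumulative surface area
between sphere and target, so vertex density follows area density and the
discrete area converges to the family's analytic value. The biconcave
family is the classical cosine-polynomial disc of diameter 7.82 μm, scaled
uniformly so the mesh volume equals the preset volume exactly.

**Reference state.** The built mesh *is* the stress-free state: per-edge
$l_0$, per-dihedral $\theta_0$, and the area/volume constraint targets are
taken from it. The preset area/volume pin the construction (volume exactly;
area through the shape family), but the discrete constraint targets must be
attainable at any mesh resolution, so they are read off the built mesh
rather than the printed continuum values. Penalties default to
$k_a = k_v = 5000$, $k_d = 100$ (model units), which hold area and volume
within 1% over $10^5$ coarse-step integrations.

## Cell–cell and cell–fluid interactions

* **RBC–RBC adhesion** (diabetic, high-fibrinogen conditions) uses the
  Morse potential
  $V_M(r) = D_e[e^{2\beta(r_0-r)} - 2e^{\beta(r_0-r)}]$ between membrane
  vertices of *distinct* RBCs, all vertices adhesive. With adhesion
  enabled, the Morse core supplies the short-range repulsion and the
  conservative DPD amplitude for that pair class is dropped — soft DPD
  repulsion at the well distance would otherwise overwhelm the
  physiologically weak attraction. With adhesion disabled the pair class
  reverts to plain repulsive DPD; the two paths are checked to coincide
  when $D_e \to 0$. Defaults ($D_e = 1\,k_BT$, $\beta = 6$ μm⁻¹,
  $r_0 = 0.3$ μm, cutoff 1.6 μm) make an isolated doublet aggregate at rest
  and separate under thermal forcing when disabled. Desk-scale channel
  runs use a shorter-ranged kernel ($\beta = 10$ μm⁻¹, $r_0 = 0.2$ μm,
  cutoff 1.0 μm) so the adhesion cutoff matches the fluid cutoff and no
  widened neighbour stencil is needed, with the per-pair well depth raised
  to $D_e = 25\,k_BT$: adhesion energy per unit *membrane area* should be
  resolution-independent, and the coarse 66-vertex mesh has
  $(l_0^{coarse}/l_0^{fine})^2 \approx 7$ times fewer vertex pairs per
  unit area than the 500-vertex mesh, so the per-pair depth scales up by
  that factor over a fine-mesh well of a few $k_BT$. The doublet fixture
  validates the kernels directly.
* **Platelets** adhere to nothing — platelet activation, adhesion and
  aggregation are outside scope — and interact with all membranes and
  walls through repulsive DPD.
* **Solvent–membrane coupling** combines reduced conservative amplitude
  (10) with elevated friction ($\gamma = 20$) for no-slip on the moving
  membrane, plus *face reflection*. Crossings are found by continuous
  collision detection against the linearly deforming triangles: with all
  four points moving linearly over a step, the point–triangle coplanarity
  function is an exact cubic in time, whose bracketed roots are bisected
  and accepted when the point lies inside the triangle at the root
  (grid-accelerated; static segment–triangle tests miss both faces
  sweeping over slow particles and crossings of rotating faces). A
  detected particle is placed back on its original side of the updated
  face plane and the approaching normal component of its face-relative
  velocity is reversed, with the opposite impulse shared by the face
  vertices — a moving-mirror reflection that conserves momentum and cannot
  pump energy. Membranes are therefore impermeable: the enclosed solvent
  count of a closed cell is conserved exactly in the validation fixture,
  with a pass-through negative control when reflection is switched off.

## Channel geometry

The parent capillary is a rectangular duct, 5 μm wide and 10 μm deep,
periodic along the flow direction. The saccular MA body is a circle of
diameter $R_1 = \mathrm{BNR}\times R_2$ in the flow plane, extruded through
the full channel depth, opening into the duct through a neck in the side
wall — the constant-depth, front-view-circle/side-view-rectangle
construction of microfluidic channels. (A spherical body was considered
and rejected: a 15 μm neck cannot open through the wall of a duct only
10 μm deep, while the extruded form reproduces the documented front and
side views consistently at every BNR.) The neck is 15 μm wide, capped at
95% of the body diameter, which binds only for the smallest body
(BNR 2.2, $R_1 = 11$ μm). The channel period defaults to
$4\max(R_1, \text{neck}) + 20$ μm so the body cannot interact with its own
periodic image; desk-scale runs shorten this to $R_1 + 17$ μm (≥ 36 μm).

Walls are a ≥ 1 cutoff thick shell of frozen DPD particles outside the
lumen plus bounce-back: solvent crossing the lumen surface is reflected
with its velocity reversed (no-slip); membrane vertices are instead
projected just inside the surface with their outward velocity component
removed, because hard position reflections at the re-entrant neck corners
feed energy into the elastic network. The duct-flow fixture validates the
combination against the analytic rectangular-duct series profile
(< 10% RMS shape deviation).

Flow is driven by a uniform body force on parent-lumen solvent — the
periodic-domain equivalent of a pressure gradient — closed-loop controlled
to a target mean inlet velocity. Because the channel's momentum relaxation
time is much longer than a measurement window, fixed-gain feedback limit
cycles; the controller instead estimates the drag time constant $\tau$ from
the momentum balance $d\bar v/dt = g - \bar v/\tau$ each window and relaxes
$g$ toward $v_\mathrm{target}/\tau$. Pulsatile driving scales the force by
$1 + A\sin(2\pi t/T)$ (default $A = 0.3$, $T = 1$ s — a cardiac-scale
cycle), whose mean over whole periods equals the static drive exactly.

## Scenario assembly and tracking

RBCs are seeded at a target hematocrit (count
$= \mathrm{round}(Ht\cdot V_\mathrm{lumen}/V_0)$) by rejection sampling:
disc normals near the width axis inside the narrow duct (the only way an
8 μm disc fits a 5 μm duct), free orientation inside the body; margins
tighten progressively for late placements since the soft cores resolve
near-contacts within the first steps. Whole-lumen or parent-only seeding is
selectable per scenario. Platelets enter at the inlet at a configured rate
(deferred, never dropped, when blocked) and recirculate through the
periodic domain. Per-cell centre-of-mass tracks are recorded at the output
cadence with a region label (parent / body); membrane coordinates are kept
unwrapped along the periodic axis so bonded terms never straddle the seam.

## Transport statistics

A *passage* is one traversal of the neck-adjacent parent segment; a
recirculating platelet accrues one passage per traversal. *Entry* is
debounced: the centre of mass must classify inside the body for ≥ 3
consecutive frames, which is robust to boundary jitter at the neck surface.
Residence time spans the maximal body-resident run; events still inside at
the end of a run are censored and reported separately, never mixed into
means — the nearly stagnant deep-lumen cells of large MAs would otherwise
dominate. Cells seeded inside the MA are excluded throughout. Entry
probability is entries over passages with a nonparametric bootstrap CI over
cells (2000 resamples); its coverage is checked against synthetic
exponential residence data. The *perfused fraction* (body voxels visited by
parent-born RBC centres over all body voxels) is an invented summary that
operationalises the qualitative perfusion contrast between small and large
MAs, and is labelled as such in outputs.

## Desk-scale fixtures: sizing and what they show

The study-scale protocol (50 million steps, 500-vertex cells, hematocrit up
to 40% in a BNR 8 channel) is cluster-scale; the package ships those
configurations but validates on reduced fixtures chosen to run on one CPU:

* geometry at true dimensions, hematocrit and driving velocities unchanged;
* solvent density 1 μm⁻³, wall shell density 1.5 μm⁻³;
* 66-vertex RBCs and 48-vertex platelets; time step 0.008; 6400 steps
  (≈ 25 ms physical) per run, ≈ 15–25 platelet passages per condition
  when pooled over seeds;
* vertex masses 3 (RBC) and 4 (platelet, desk-scale 3× RBC stiffness): the
  integration step is set by the stiffest bond frequency
  $\omega \approx \sqrt{6k_\mathrm{edge}/m}$, so the full 100×-stiff
  platelet preset cannot run at the coarse step (it is exercised at a finer
  step in its own fixture). Both stiffness reduction and vertex mass are
  kept minimal: excess membrane inertia measurably suppresses the
  collision-driven lateral platelet motion that carries platelets into the
  aneurysm, and at 3× the platelet remains effectively rigid relative to
  the red cells at these stresses;
* all hematocrit levels share the whole-lumen RBC seeding protocol in the
  transport comparisons; parent-only seeding is reserved for
  perfusion-style studies of how far inflowing blood reaches.

Consequences: absolute entry probabilities and residence times at this
scale are *not* comparable to study-scale magnitudes — cell Reynolds
number, membrane inertia and counting statistics all differ — so the trend
suite asserts *orderings* across conditions (larger body, faster inlet,
adhesion on, higher hematocrit), pooled over seeds, never magnitudes.
Residence times deserve a caveat of their own: the recirculation vortex
inside an aneurysm body turns over on a timescale roughly ten times the
desk-scale run window, so essentially every entry is right-censored — a
faithful miniature of the study-scale observation that cells linger for
large fractions of a second. Conditional means over completed events are
therefore not measurable at this scale; the residence-based ordering
(platelets linger, red cells do not) is asserted on the mean *observed*
in-body time per passage, a censoring-robust lower-bound surrogate that
the event records expose alongside the completed-event residence. Passing
trends demonstrate that the implemented mechanisms point the right way,
not that desk-scale numbers transfer to physiology.

A note on statistical resolution: at the shipped run lengths each
condition accrues on the order of sixty platelet passages, so the suite
resolves entry-probability differences of roughly 0.06 and cannot rank
conditions that differ by one or two entry events. Mechanisms that act
through quickly-established collision statistics — adhesion-driven
aggregation, the hematocrit dependence of the collision rate — separate
cleanly at this scale. Mechanisms that rely on the slowly-developing
marginated core structure of the suspension (the body-size and
inlet-velocity dependence of large-aneurysm entry) need either several
times more passages or pre-marginated initial states to resolve, and a
fresh randomly-seeded suspension has neither within a 25 ms window; the
corresponding orderings are asserted regardless and report honestly when
the sample cannot establish them. Features of real
blood that the generator does not emulate at all: plasma protein rheology,
platelet activation and shape change, wall compliance, and oxygen
transport.

## Numerical choices and degenerate inputs

* Coincident particles, zero-length separation vectors, non-finite forces,
  edges at the WLC divergence, degenerate triangles, open meshes, cutoffs
  exceeding half a periodic box, walls thinner than the fluid cutoff, and
  zero-passage probability requests all raise informative errors rather
  than propagating garbage.
* Runs are bit-reproducible per seed (single-threaded, own PCG32 stream
  carried in checkpoints); checkpoint-resume equals the uninterrupted run
  exactly, and an instability detector (speed threshold) aborts with the
  last stable state retained.
* Ties and boundary cases: the neck surface belongs to the parent side;
  classification is deterministic, and a continuous parent-to-body path
  flips exactly at the neck surface.

## Known limitations

* The desk-scale fluid at density 1 is marginally compressible and its
  viscosity places cell-scale Reynolds numbers well above the true
  microcirculation values; this is the standard DPD trade-off and the
  reason trend-level claims only.
* The wall model imposes no-slip in a time-averaged sense; a thin
  near-wall density oscillation of about one particle diameter is
  inherent to frozen-particle walls.
* Entry detection by centre of mass under-counts shallow grazing entries
  of large cells; the debounce length and the cadence are exposed so the
  sensitivity can be probed.
* The six-scenario preset grid covers the study design, not a general
  parameter sweep; per-scenario overrides go through `simulation_config()`.
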