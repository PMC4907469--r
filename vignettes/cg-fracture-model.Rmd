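---
title: "A coarse-grained fracture model for apatite-collagen composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained fracture model for apatite-collagen composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Enamel-like apatite-protein composites resist fracture far better than
pure apatite: instead of a single crack running through the sample, load
beyond the elastic limit is dissipated into many arrested micro-cracks.
`cgfrac` implements a minimal two-dimensional particle model of this
behaviour. The material is divided into hexagonally packed *building
blocks*, each standing for one collagen triple-helix embedded in a
10×10×10-unit-cell hydroxyapatite prism (the position of a block is
tracked only in the xy plane; the third dimension is implicitly
periodic). A block is about 9.17 nm across, so a 300×300 sample is
roughly 3 μm wide — micrometre-scale mechanics from nanometre-scale
ingredients.

Bonded neighbours interact through a **truncated-harmonic pair
potential**

$$V(r) = k\left[(r - r_o)^2 - (r_c - r_o)^2\right] \;\; (r \le r_c),
\qquad V(r) = 0 \;\; (r > r_c),$$

a parabola shifted so that it reaches zero exactly at a rupture cutoff
$r_c$. The single functional form encodes both linear elasticity (near
$r_o$) and brittle bond rupture (beyond $r_c$ the bond transmits no
force). Two species of block exist:

| species | $k$ (kJ mol⁻¹ nm⁻²) | $r_o$ (nm) | $r_c$ (nm) |
|---|---|---|---|
| pristine (P) | 1.77·10⁵ | 9.17 | 9.65 |
| damaged (D)  | 1.10·10⁵ | 9.35 | 9.82 |

The damaged species — standing for composite material that has undergone
plastic deformation at the organic-inorganic interface — is softer and
has a larger equilibrium distance. **Damage is irreversible**: whenever a
pristine block has at least one bonded neighbour at separation
$\ge r_c^P = 9.65$ nm, it switches to the damaged species and never
reverts (self-healing operates on far longer time-scales than damage
acquisition and is neglected). The pristine potential applies only
between two pristine blocks; any pair involving a damaged block uses the
damaged potential. We read the "entirely undamaged neighbourhood"
condition as a pair-species rule because it is local, symmetric in the
pair, and independent of evaluation order; the stricter alternative (a
pristine block bordering a damaged one interacts softly even with its
pristine neighbours) would make the force law depend on third parties.

The loading protocol is **strain-and-hold**: an instantaneous affine
deformation (default 5% along x) followed by relaxation dynamics at
constant strain, the setup commonly used in loading experiments. During
the hold, stress relaxes by micro-crack formation; the package records
the virial stress trace, every switching event, every broken bond with
its first-breakage step, clusters the broken bonds into cracks, and fits
the exponential decay of the stress.

## Parameters that matter

* `spacing` / $r_o^P$ = 9.17 nm — the pristine block size; lattices are
  built at this spacing so a defect-free pristine sample starts in
  mechanical equilibrium.
* strain magnitude, default 0.05 — below the uniform rupture threshold
  $(r_c^P - r_o^P)/r_o^P = 5.234\%$, so a defect-free sample under 5%
  strain breaks no bond; fracture requires a stress concentrator.
  Strains above 0.2 trigger a validity warning.
* time step, default 350 fs — with the default block mass (below) the
  bond vibration period is $2\pi\sqrt{m/2k_P} \approx 10.6$ ps, about 30
  time steps, comfortably stable for velocity-Verlet integration.
* block mass, default 10⁶ amu — the order of magnitude of a
  10×10×10-unit-cell hydroxyapatite prism plus one collagen
  triple-helix. The mass sets the time-scale only; equilibrium
  geometries, rupture thresholds and crack patterns do not depend on it.
* temperature (default 300 K) and Langevin friction (default 0.1 ps⁻¹)
  — at 300 K thermal displacements are ~0.003 nm, small against the
  0.02 nm margin between the strained bond length and the cutoff, so
  thermal noise perturbs but does not drive fracture. Zero temperature
  with positive friction gives pure damped relaxation; zero friction
  gives microcanonical dynamics (energy drift < 10⁻⁴ relative over 10⁴
  steps in the tests).

Units: nm, kJ/mol, amu (g/mol), ps internally (time steps are specified
in fs; 1 kJ/mol = 1 amu·nm²/ps², so no conversion constants appear in
the integrator). Stress is the 2-D virial,
$\sigma_{ab} = (\sum_\text{bonds} r_a F_b + \sum_\text{blocks} m v_a
v_b)/A$, in kJ mol⁻¹ nm⁻², with the pressure-positive sign convention
(a sample under tension has $\sigma_{xx} < 0$); grip blocks are excluded
from the kinetic sum, and $A$ is the current bounding-box area.

## Design choices where the model was open

**Boundary conditions.** Grips are needed to hold the strain. We clamp
the leftmost and rightmost block columns *along the loading axis only*
(roller grips): their x coordinates are frozen at the strained values,
their y coordinates remain free degrees of freedom. Full x+y clamping
was tried first and rejected for a physical reason discovered in
testing: it blocks Poisson contraction at the grips, which concentrates
stress at the grip corners strongly enough to rupture bonds there even
quasi-statically at 5% strain — spurious damage that competes with the
notch as a crack source and breaks the sub-threshold guarantee. With
roller grips the affinely strained defect-free lattice keeps every
horizontal bond at 9.6285 nm < 9.65 nm and every diagonal bond shorter
still, so no bond ruptures without a defect, exactly as the printed
constants imply. Periodic horizontal boundaries are available as a
configuration option (`boundary: periodic_x`).

**Notch geometry.** The crack-initiating surface imperfection is
modelled as a rectangular notch (default 4 blocks wide, 2 rows deep)
cut into the top free surface; width, depth and position are
configurable. Only its role as a stress concentrator matters for the
observables reported here.

**Switching cadence.** Species are updated once per integration step,
after the position update; all switches implied by the new positions are
applied simultaneously (no ordering dependence), and forces are
refreshed before the next step so every force evaluation sees one
consistent species assignment.

**Broken bonds stay in the topology.** A bond beyond its cutoff exerts
zero force but is kept in the bond list: the force law remains a pure
function of distance and species, and the bond is flagged broken (with
the step of first breakage, never unset) for crack analysis. If the pair
re-enters the — by then damaged-species — cutoff it transmits force
again. Forces act only along the initial bond topology; the cutoffs
(9.65/9.82 nm) lie far below the second-neighbour distance
($\sqrt3 \times 9.17 \approx 15.9$ nm), so for intact material the
topology and a distance criterion coincide, and no dynamic re-bonding
is needed. There is no excluded-volume repulsion between never-bonded
blocks; the loading scenario is tensile and block overlap does not
arise at the strains considered. Both simplifications are limitations
for compressive or large-strain scenarios.

**Crack clustering.** Broken bonds are nodes; bonds sharing a block, or
with midpoints within one lattice spacing, belong to the same crack (the
midpoint rule keeps a bifurcating crack separated by one intact bond
connected as a single branched cluster). Connected components are
computed with igraph. A cluster *percolates* if its bounding extent
spans the full free sample height transverse to the load — the
discrete analogue of a continuous fracture line, i.e. material failure;
both axes' spans are reported.

**Decay fitting.** $\sigma(t) = c + a\,e^{-t/\tau}$ is fitted by
bounded Levenberg-Marquardt (`minpack.lm`), $\tau > 0$. $R^2$ is
computed on the raw series, not a log transform, because the offset can
be near zero. Start values come from the series tail (offset), head
(amplitude) and a log-linear regression (decay time), with a ladder of
fallback starts because stress traces often show a fast initial drop
followed by a slow tail, which can strand a single far-off start. A
series with numerically zero variance is reported as a degenerate fit
(amplitude 0, flagged) rather than an error.

**Potential fitting.** The model-reduction step — fitting the
truncated harmonic to a tabulated energy-distance profile — treats the
cutoff as a non-smooth parameter: $r_c$ is found by grid search, and at
each candidate $k$ and $r_o$ come from constrained linear least squares
with $V(r_c) = 0$ enforced exactly. Points beyond a candidate cutoff
are predicted as zero and their residuals counted, so candidates with
different point splits compete on one total. A winning candidate at a
grid edge is flagged (`boundary_solution`): profiles without a rupture
signature (no zero-energy plateau) have no interior optimum, and the
flag tells the user the cutoff was not identified. Synthetic profiles
for validating this machinery are generated from known potentials with
optional Gaussian noise; they emulate the shape of energy-versus-stretch
curves from finer-grained simulations, not any measured curve, so
passing recovery tests validates the fitting machinery — not the
original atomistic-to-CG reduction, which requires atomistic data that
is out of scope here.

## What the tests do and do not show

The test suite and the acceptance script work entirely on lattices and
profiles generated in code from the model constants. Problem sizes were
chosen to keep every check on a single desk-scale CPU: equilibrium
geometry on 30×30 lattices (force tolerance 10⁻⁶ kJ mol⁻¹ nm⁻¹), the
relaxation experiment on a notched 100×100 lattice held for 60,000
steps (21 ns) with observables every 200 steps, and its
zero-temperature control for 30,000 steps. At this size the stress
trace reaches its plateau well inside the run: it decays by more than
an order of magnitude ($\sigma_\text{final}/\sigma_\text{initial}
\le 0.1$), is well described by a single exponential ($R^2 > 0.9$), and
leaves a non-percolating pattern of hundreds of micro-crack clusters —
the same qualitative picture as the full-scale 300×300, 7 μs
experiment, at roughly a hundredth of the cost. The 100×100 sample is,
however, only ~1 μm wide: absolute crack lengths and decay times are
not converged with respect to sample size and should be read as
scaled-down, not quantitative, replications.

Two further honest caveats. First, crack *paths* in bond-breaking
lattice models are chaotic: once a cascade of ruptures is underway,
halving the time step (or changing the seed) changes which bonds break,
even though counts, stress plateaus and percolation behaviour are
robust. The time-step convergence test therefore uses an
arresting-crack benchmark (strain 4%, where the notch breaks a bond and
the crack stops) on which the outcome is bitwise dt-robust. Second, the
model is athermal in spirit: fracture statistics at 300 K and at 0 K
with a notch are similar, and nothing in the tests probes
thermally-activated crack nucleation over barriers.

## Known limitations

* Strictly 2-D; no prism stacking, plate bending, or angular terms.
* Single-crystal block arrangement only — no polycrystalline disorder,
  no explicit collagen orientation within a block.
* No finite strain-rate ramp for the coarse-grained protocol: strain is
  applied instantaneously, as in the strain-and-hold experiment the
  model replicates.
* The conversion from per-area energy curves of a finer-grained model
  to per-bond profiles is the user's responsibility (a scale factor);
  the package fits whatever per-contact profile it is given.
* Block identifiers are 1-based, following R convention.
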