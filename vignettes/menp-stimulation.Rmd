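---
title: "Modeling magnetoelectric nanoparticle stimulation of a CA1 neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling magnetoelectric nanoparticle stimulation of a CA1 neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menpstim)
```

`menpstim` simulates how magnetoelectric nanoparticles (MENPs) — core–shell
composites whose surface develops a dipolar electric potential under an
applied magnetic field — stimulate a CA1 pyramidal neuron. This vignette
explains the model, its assumptions, the tunable parameters and their
defaults, what the synthetic data emulate, the numerical choices, and the
known limitations. Units are fixed package-wide: µm, mV, ms, S/m;
conversions happen only at file boundaries.

## The field model

A polarized MENP is abstracted as a *split sphere*: an upper hemispherical
cap at +V₀ and a lower cap at −V₀ (default V₀ = 5 mV, a representative
magnetoelectric output near magnetic saturation), separated by an
insulating equatorial band held at 0 mV. The surrounding medium is
homogeneous, isotropic grey matter (σ = 0.333 S/m). Under the quasi-static
approximation — valid at the stimulation frequencies used here, where
ohmic currents dominate displacement currents — the exterior potential is
the solution of the Dirichlet problem for Laplace's equation:

$$V(r,\theta) = \sum_{l\ \mathrm{odd}} A_l \left(\frac{R}{r}\right)^{l+1}
P_l(\cos\theta), \qquad
A_l = \frac{2l+1}{2}\int_{-1}^{1} V_{\mathrm{surf}}(u)\,P_l(u)\,du ,$$

with only odd degrees surviving the antisymmetric boundary condition. We
solve this analytically rather than with a finite-element discretization:
in a homogeneous isotropic medium the series *is* the solution of the same
boundary-value problem, it removes meshing entirely, and superposition
over many particles is exact. The conductivity does not enter the
potential (it cancels in the homogeneous Dirichlet problem) and is kept
only for current-density queries. Consequences of this choice:

- The simulation-box bounds of the conductive block (1 × 1 × 1.5 mm³ by
  default) are metadata only: at ≥ 100× the source size, boundary effects on
  the analytic free-space solution are negligible.
- The insulating band defaults to a zero-width sign discontinuity; a
  finite `band_halfwidth` imposes V = 0 on the band by the same
  projection. The band's mixed (Neumann) character is not modeled.
- The series is truncated at `max_degree = 51`. Gibbs oscillation from
  the cap discontinuity is confined to r < 1.1R; all neuron nodes sit at
  least one gap (≥ 10 nm) outside the surface, and doubling the
  truncation moves potentials at r ≥ 1.1R by < 0.1% (tested).

Coefficients are computed by Gauss–Legendre quadrature with enough nodes
to be exact for the polynomial integrands; the electric field is the
analytic gradient of the truncated series.

Sources are placed against a target segment node in three canonical
orientations: **perpendicular negative** (cathodic vertex facing the
node), **perpendicular positive** (anodic vertex facing the node), and
**parallel** (dipole axis along the segment). The gap is always the
node-to-surface distance. For the parallel orientation more than one
lateral convention is geometrically possible; we adopt the one where the
equatorial plane contains the target node, with the centre displaced
laterally by gap + radius.

## Morphology

A morphology is a tree of unbranched cable *sections*, each a 3D polyline
with per-point diameters, discretized into `nseg` equal-arclength
*segments* (two per section by default, matching the convention of
two-segment sections with biophysics lumped at segment centres, the
*nodes*). SWC is the interchange format; note SWC stores points, not
section boundaries, so consecutive unbranched same-type sections merge on
read — round trips preserve geometry, lengths and topology, not the
section partition.

Because no reconstruction can be downloaded at build or test time, the
package generates a synthetic CA1-like morphology (`make_ca1_like()`). It
reproduces the compartment *inventory* the experiments need — one soma
(20 µm cylinder), a straight 400 µm axon, four basal dendrites (150 µm,
tapering from 2 µm at the soma to 0.6 µm at the tip), a connector and an
apical trunk with two terminal branches — and makes no attempt to match
the 178-section count or branching statistics of a real reconstruction.
Two geometric choices matter for the physics:

- **Basal taper.** Distal basal segments are thin, so their local sodium
  conductance exceeds the axial load and a local spike can ignite there;
  the widening toward the soma imposes a geometric-ratio failure, so
  dendritic spikes die out before the soma instead of invading the axon.
  This is what makes "dendrite-confined" outcomes possible at all.
- **Segment lengths** (≈ 66 µm axonal, ≈ 37 µm basal) set the local
  charge-redistribution time constants and hence how faithfully each
  node's membrane potential tracks a rapidly oscillating extracellular
  potential; they shape the high-frequency end of the frequency sweep.

## Membrane biophysics

Passive properties are uniform: R_m = 28 kΩ·cm², R_a = 150 Ω·cm,
C_m = 1 µF/cm² (so τ_m = R_m·C_m = 28 ms, enforced at config load) and
V_rest = −65 mV. A leak conductance 1/R_m with a per-node *solved* leak
reversal makes −65 mV an exact equilibrium whatever the active channel
densities — the package's way of honouring a stated resting potential
without hand-balancing window currents (a 200 ms free run drifts by
< 10⁻⁹ mV).

The active set is named (Na, KDR, KA, Ih) but its kinetics are the
package's own: every gate uses a Boltzmann steady state
$x_\infty(V) = (1+e^{-(V-V_{1/2})/k})^{-1}$ and a bell-shaped (or
saturating) time constant, with all parameters in
`inst/extdata/ca1_membrane.yaml`. The shipped configuration was chosen so
that the qualitative behaviour of the stimulation experiments emerges
from known CA1 physiology:

- **Axonal Na** (`na`, m³h): high density, fast activation, and
  inactivation that is fast at depolarized voltages but recovers slowly
  below −70 mV. This produces accommodation: slow depolarizing ramps and
  sustained (biased or rectified) depolarization inactivate the axon,
  while brief mid-frequency cathodic phases fire it.
- **Axonal D-type K** (`kd`, a⁴b): activates in ≈ 0.8 ms with very slow
  inactivation, clamping multi-millisecond ramps (low-frequency phases)
  that the fourth-power gate barely notices during ≈ 1 ms phases. This is
  the classic Kv1-like threshold guard of the axon initial segment.
- **Dendritic Na** (`nad`, m³h): slowly activating (τ_m ≈ 3 ms),
  slowly and incompletely inactivating. Dendrites therefore respond to
  slow, sustained depolarization (low frequencies, static bias) and are
  comparatively blind to brief phases.
- **Dendritic M-type K** (`km`, u²) with τ ≈ 6 ms tracks the *mean*
  depolarization and vetoes slow rectified buildup at mid frequencies,
  while large low-frequency phase peaks and heavily filtered 10 kHz
  responses ride over it.
- **KDR** (n⁴) repolarizes spikes; **KA** (a⁴b) adds a fast transient
  brake in dendrites and soma; **Ih** is small and mostly sets a slight
  sag. A linear-in-distance density rule is available
  (`gbar_slope_per_um`) but defaults to uniform per compartment kind.

Temperature is fixed (any Q10 factors are folded into the constants).

## Cable engine

The spatially discretized cable equation on the segment tree is

$$C_j \frac{dV_j}{dt} = -\sum_c g_{c,j}(V_j - E_c) - g_L (V_j - E_{L,j})
+ \sum_{k \sim j} g_{jk}\,[(V_k - V_j) + (V^e_k - V^e_j)] ,$$

with axial conductances
$g_{jk} = 1/(R_a (L_j/2A_j + L_k/2A_k))$ between connected nodes. The
extracellular potential enters only through *differences* across
connected nodes — the solver-level equivalent of the activating function,
valid on bent and branched neurites where the straight-fiber second
derivative is not. Gauge invariance (adding a constant to every node's
V_e changes nothing) is tested. The quasi-static separation is exact in
the implementation: the static pattern V_j is computed once per source
configuration and scaled in time by AC·(a(t) + bias/V₀).

Integration is backward Euler with gates advanced by exponential
relaxation at the frozen previous voltage, and the per-step linear system
is solved exactly in O(n) by Hines elimination on the tree (implemented
in C++). Defaults: dt = 0.025 ms, tightened automatically so every
stimulus period keeps ≥ 40 steps (0.0025 ms at 10 kHz). The integrator
and step are the package's own choices, validated by closed-form checks (steady finite-cable cosh profile to < 1%, τ_m
recovery to < 0.1%, dt-halving moving peaks < 0.5%, agreement with a
dense explicit RK4 oracle on a small passive system).

## Protocols

**Waveforms.** `one_period_sine` (duration locked to 1000/f ms; the
single-period 100 Hz pulse used for single-source titration) and
`sine_burst` (fixed duration, default 100 ms, for summation protocols). A static bias
b (mV) adds b/V₀ to the normalized modulator, so it scales with AC
exactly as the oscillation does; the alternative (un-titrated bias) would
break the single-multiplier structure of the titration equation.

**Spike detection** is the first crossing of rest + 80 mV (i.e. +15 mV),
per node. **Classification**: axonal spike if any axonal node crossed;
dendrite-confined if only dendritic nodes crossed; the initiation site is
the earliest crossing (ties to the lowest node id).

**Titration** finds the minimal AC whose simulation satisfies a success
predicate, by testing the lower bound, doubling the upper bound until
success (capped at 10⁶), then geometric bisection to 1% relative
tolerance; plateaus resolve toward the smaller AC. The experiment drivers
titrate with the *any-spike* predicate and then classify the outcome at
threshold — this is the only reading that reproduces tables where
dendrite-confined rows carry their own finite threshold.

**Activating function**: uniform resampling (default 0.01 µm) of the
potential along the axon line, central second difference, endpoints
dropped — exact for quadratics. The experiment drivers compute it only
for the nanometric source over the straight axon, where the localized
field justifies the straight-fiber approximation; the wide cluster field
reaches bent sections and the AF reading is not meaningful there.

## What the synthetic experiments show — and what they cannot

On the synthetic morphology with the shipped membrane, the drivers
show the qualitative structure expected of MENP stimulation: the cathodic
(perpendicular-negative) orientation gives a central depolarizing
activating-function lobe with flanking hyperpolarization, the anodic
orientation the mirror image, and the parallel orientation a biphasic
pair; doubling the gap from 1r to 2r halves the field peak and broadens
the profile; the 10 µm cluster spreads its field two orders of magnitude
farther along the axon than the 100 nm particle; the three-source
frequency sweep shows dendrite-confined outcomes at 50–100 Hz, axonal
initiation in a 250–750 Hz band, and dendrite-confined outcomes again at
10 kHz; and the titrated AC falls monotonically with static bias,
dropping below 1 at 40 mV.

These are *structural* reproductions, not numerical ones. Absolute
amplification coefficients depend on the morphology's segment lengths and
on channel kinetics that the package defines itself; they are not expected
to match numbers obtained with any specific reconstructed morphology and
its own channel files. Passing tests on the
synthetic cell therefore validate the pipeline's physics and logic, not
any particular biological neuron.

Two further properties deserve explicit caution, because they follow from
the threshold-crossing definition of a "spike":

- A sharply localized extracellular potential polarizes the membrane
  directly (for features much narrower than the length constant,
  V_m ≈ −V_e at the driven node, within a sub-millisecond local time
  constant). At sufficiently large AC this forced polarization alone
  crosses any fixed depolarization threshold — even on a purely passive
  membrane, and even for the anodic orientation (whose second sine
  half-period is cathodic). A detector based on action-potential shape
  rather than level crossing would behave differently; the package
  implements the stated level-crossing criterion.
- Because of the same effect, titration thresholds for strongly coupled
  configurations partly reflect forced polarization rather than purely
  regenerative excitation — as they do in any model with this detection
  rule.

## Numerical and testing choices

Problem sizes were chosen to keep the full test suite and the acceptance
script comfortably fast while leaving the physics intact: the synthetic
CA1 tree has 21 sections (42 nodes), sweeps use the canonical frequency
and bias grids, titration uses 1% tolerance, and closed-form cable checks
use a 200-node passive cable. Everything is deterministic; the only RNG
use is the optional morphology jitter, which restores the global seed
state after use.
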