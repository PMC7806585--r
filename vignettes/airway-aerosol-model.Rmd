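---
title: "A reduced-order model of airflow and aerosol deposition in the conducting airways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of airflow and aerosol deposition in the conducting airways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaydep)
```

## Scope and idea

`airwaydep` models the inhalation of therapeutic aerosol (3–25 µm) under
sedentary breathing, from the mouth to the sixth bronchial generation, at
desk scale. Where a full CFD treatment would resolve the three-dimensional
velocity field and integrate particle drag along resolved trajectories,
this package deliberately collapses each of those stages onto its standard
reduced-order surrogate:

* the geometry is a **characteristic airway tree** — an averaged, rule-built
  anatomy rather than a patient-specific one — with an elliptical upper
  airway, a C-shaped ringed trachea and an asymmetric bifurcating tree;
* the airflow is a **quasi-steady laminar Poiseuille network** driven by the
  sinusoidal breathing waveform;
* particle capture is evaluated with **empirical deposition-efficiency (DE)
  correlations** in the Stokes number (tracheobronchial tree) and the
  impaction parameter (upper airway), applied along an exactly advected
  one-dimensional bolus.

The correlation forms are the same ones 3D particle-tracking studies use to
validate themselves, which is what makes them a defensible surrogate for the
full discrete-phase model: the pipeline reproduces regional/total DE trends,
injection-time sweeps and per-lobe escape accounting, not velocity fields,
vortices or exact 3D deposition percentages.

## The geometry

### Bifurcation design rules

Branch calibres follow the diameter law
$d_P^{x_n} = d_A^{x_n} + d_B^{x_n}$ relating a parent to its two daughters.
The exponent is not fixed by the study conditions; we default to
$x_n = 3$ (Murray's law, the energetically optimal value for laminar flow)
and make it configurable. When a measured morphometry table is supplied,
the law is *not* enforced — `build_tree()` reports the relative residual
$|d_P^{x_n} - d_A^{x_n} - d_B^{x_n}|/d_P^{x_n}$ per bifurcation as a
diagnostic instead, because real anatomies deviate from any single
exponent.

Two further rules shape each bifurcation: the transition zone begins at
80 % of the parent's axial length (`transition_fraction = 0.8`), and the
carinal ridge is rounded with radius $r_c = (R_A + R_B)\,c_c$, $c_c = 0.1$.
In this reduced-order setting both are geometric annotations: they are
consumed by the surface export and by anyone lofting the geometry, but the
1D network flow cannot feel them.

### Trachea and rings

The trachea is a circular tube of diameter 1.56 cm cut by a posterior plane
0.65 cm from the centre — the C-shape left by the *pars membranacea*. The
cut area (`c_shape_area()`, ≈ 1.835 cm² against 1.911 cm² for the full
circle) is used as the effective cross-section for velocities, Reynolds
numbers and dynamic-head losses; the *network resistance* still uses the
circular diameter, a documented simplification (the exact friction factor
of a C-section lies within a few percent of the circular value at these
Reynolds numbers, well inside the loss-model uncertainty).

Cartilaginous rings are annotated on the trachea and main bronchi at a
regular step (defaults: step 5.4 mm, width 3.5 mm, depth 0.45 mm —
characteristic adult values; all overridable). Rings are sub-millimetric
wall features; there is no accepted reduced-order model of their effect on
the boundary layer, so by default they do not alter flow or deposition. An
optional *effective roughness* mode subtracts the ring depth from the
effective tracheal diameter for users who want a bounding estimate; it is
off by default.

### Upper airway

The oral cavity, pharynx and larynx are elliptical tubes anchored at
cross-sectional areas of 2.98, 0.95 and 0.64 cm² (the glottal minimum).
All sections are rescaled by one geometric factor so the cast's upper
tracheal diameter (1.9 cm) meets the model's 1.56 cm trachea:
$s = 1.56/1.9 \approx 0.821$. The exact factor used by any particular cast
study is unrecoverable; matching diameters at the junction is the natural
choice and is exposed as `scale_mode`. Hydraulic diameters of ellipses use
$D_h = 4A/P$ with Ramanujan's perimeter approximation.

### The packaged characteristic tree

`make_characteristic_table()` emulates a cast-derived digital airway model
without downloading anything. Its design target is functional, not
coordinate-wise: the equal-pressure flow split on the resulting Poiseuille
network must reproduce the reference lobar ventilation partition
(RUL 19 / RML 9 / RLL 29 / LUL 26 / LLL 17 %, right lung 57 %).

The construction: trachea → right/left main bronchi (1.30/2.2 and
1.17/5.0 cm diameter/length — the right wider and shorter, which is where
the right-favouring asymmetry physically lives) → lobar roots (RUL, LUL,
LLL at generation 2; RML, RLL at generation 3 below a 1.00/2.5 cm bronchus
intermedius) → symmetric $x_n = 3$ subdivision with length = 3 diameters
down to generation 6, giving 64 peripheral outlets. A subtree built this
way has the closed-form effective resistance $(7-k)\cdot R_{\text{root}}$
for a root at generation $k$, so the four free lobar-root diameters are
*derived*, not searched: `characteristic_dimensions()` inverts the
parallel-resistor algebra so the target split holds by construction. The
one-time tuning is frozen in code and in `inst/extdata/PROVENANCE.md`; the
packaged CSV fixture is byte-identical to the generator output and
checksummed (content-addressed), which a regression test asserts.

What the generator does *not* emulate: real centreline curvature and
cross-section irregularity, cartilage-deformed lumen shapes, and the
coordinate set of any specific cast. Tests passing on this fixture
therefore certify the pipeline's mechanics and its calibrated operating
point, not anatomical fidelity beyond the ventilation partition.

## The flow model

### Waveform

Sedentary breathing is a 4 s sinusoid, $Q(t) = Q_{pk}\sin(2\pi t/T)$,
inhalation on $[0, T/2]$. For a half-sine the peak is $\pi/2$ times the
mean: a 6 L/min mean inspiratory flow peaks at 9.42 L/min. Both numbers are
derived, not stored, so they stay consistent under reconfiguration.

### Quasi-steady Poiseuille network

Each instant of the cycle is an independent steady solve
(`solve_transient()` is a scaling of `solve_steady()`): at 0.25 Hz the
Womersley number of even the trachea is small and flow-field inertia is
negligible — the classic quasi-steady regime. This is a documented
limitation: flow separation, the laryngeal jet's structure and secondary
vortices are outside the model.

Two outlet boundary conditions are provided. `equal_pressure` (the default
for validation) lets the split emerge from the network: daughter flows are
inversely proportional to daughter-subtree effective resistance, computed
by post-order recursion; this is the mode under which the packaged tree
reproduces the reference split. `lobar_fractions` pins the per-lobe
partition exactly (distributed equally within a lobe), for deposition
studies that want the published ventilation imposed. Because the split of
a linear resistor network is flow-independent, the per-branch fractions
are computed once; mass is conserved at every node to round-off, which the
property suite checks at 1e-10.

### Losses: why pure Poiseuille is not enough, and the calibration

Fully developed Poiseuille flow underestimates the pressure drop of a
branching network at physiological Reynolds numbers — entrance lengths are
comparable to branch lengths, and junctions dissipate extra energy. Two
standard corrections carry this:

* the **Pedley entrance-flow factor**
  $Z = \max\!\big(1, \tfrac{C}{4\sqrt2}\sqrt{Re\,d/L}\big)$, $C = 1.85$
  (the canonical constant), multiplying each branch's viscous drop;
* **dynamic-head junction losses** $K\rho U|U|/2$ at each bifurcation
  entry and at the larynx (the glottal jet), with `K_larynx = 1`.

The junction coefficient is the model's one calibrated constant:
`K_bifurcation = 2.2` is chosen once so that the trachea-inlet to
generation-6 static drop at the inspiratory peak reproduces the reference
value of about 4.5 Pa on the characteristic tree (pure Poiseuille gives
≈ 0.9 Pa; Pedley alone ≈ 2.6 Pa). The calibration lives in
`loss_config()` / `default_config.yaml`, not in the solver.

Because the minor losses are nonlinear in $Q$, they enter the *pressure
accumulation* only; the flow split stays that of the linear network. This
quasi-linear treatment keeps the split exact and reproducible and is
consistent with how multiple-path dosimetry models treat losses.

The glottal Reynolds number is reported from the scaled larynx ellipse at
the instantaneous flow; for an ellipse $Re = 4\rho Q/(\mu P)$ depends only
on the perimeter, so the value is a direct function of the documented
upper-airway scaling.

## The aerosol model

### Dimensionless groups and correlations

Impaction is the dominant mechanism for 3–25 µm particles at these flows.
The tracheobronchial regions use
$DE = 1 - \exp(-a\,St^{b})$ with
$St = \rho_p d_p^2 U C_c/(36\mu R_0)$ evaluated with the *parent* branch's
mean velocity and radius at region entry; the upper airway uses
$DE = 1 - \exp(-a\,IP)$ with $IP = \rho d_p^2 Q$ in its conventional units
(g/cm³ · µm² · L/min). Particles default to water density 998.2 kg/m³ and
$C_c = 1$, appropriate above a micrometre.

The per-region constants are **configuration, not physics shipped as
fact**: no study prints them for this exact geometry. The packaged YAML
(`deposition_correlations.yaml`) sets plausible impaction-fit magnitudes —
upper-airway $a$ of order 1e-4 per IP unit rising to 4e-4 at the glottal
jet, tracheobronchial $a$ of order 1–5 with exponents $b$ = 1.15–1.3,
slightly above one as impaction fits are — and every constant is
overridable through the config file. Choosing $b > 1$ makes DE convex in
the flow, which is what lets an unsteady cycle out-deposit its mean flow
(Jensen's inequality); that behaviour is a property of impaction fits, not
a tuning aimed at any particular number.

### Exact event-driven bolus advection

Transport is one-dimensional: a bolus occupies a position along a conduit
(upper-airway section or branch) and moves at the local mean velocity
$u_c(t) = A_c \sin(\omega t)$, with $A_c$ fixed by the conduit's flow
fraction and area. Integrating the sinusoid gives positions in closed
form, so conduit-crossing times come from a cosine inversion rather than
time-stepping — the advection is exact to round-off and has no $\Delta t$
convergence parameter. (The flow *reports* use a default 0.01 s sampling;
transport does not.)

Rules at events, in order:

* **region entry** (forward or backward): the entering weight is recorded
  in the region's denominator, then the region's correlation is applied —
  St from the conduit being left, IP from the instantaneous flow of the
  conduit being entered. Re-entries during exhalation count again: a
  particle passing the larynx twice gets two capture opportunities, which
  is the physical reading of a per-pass efficiency.
* **bifurcation**: the bolus splits in proportion to the instantaneous
  daughter flows (their ratio is time-independent). Deterministic mode
  splits weights; Monte-Carlo mode samples the route.
* **peripheral outlet during inhalation**: the weight escapes, credited to
  the branch's lobe (escaped aerosol is available to the deeper airways
  the model does not resolve).
* **flow reversal at T/2**: in-flight boluses stall and advect backward;
  a bolus reaching the mouth is recorded as *exhaled*. The conservation
  ledger folds exhaled into suspended, keeping
  deposited + escaped + suspended = 1 (checked to 1e-9 on every run).
* **end of cycle**: remaining in-domain weight is suspended.

Deterministic fractional-bolus accounting is the default because it is
reproducible and variance-free; the seeded Monte-Carlo mode exists for
per-particle position-fate maps (each of the 2720 disk positions is
returned with its fate) and is statistically identical to the
deterministic expectation — the suite checks agreement within three
binomial standard errors at n = 2720, and bit-reproducibility under a
fixed seed. The injection sampler snapshots and restores the global RNG
state, so library use never perturbs a caller's random stream.

Gravitational sedimentation (exponential inclined-tube formula per conduit
transit, using each branch's gravity angle) is available but **off by
default**; Brownian diffusion is not implemented because it is negligible
above ~1 µm. Both choices reflect the impaction-dominated size range the
model targets.

### Injection-time analyses

`injection_sweep()` injects the oral-disk bolus every 0.2 s over 0–1.8 s
(ten runs). `steady_vs_transient()` compares constant-flow DE with the
cycle-averaged sweep (the arithmetic mean over the grid — the natural
desk-scale reading of "deposition over a breathing cycle") and reports the
best single injection time. Injections during exhalation are rejected
rather than modelled. The qualitative behaviours the acceptance suite
checks — laryngeal DE rising with size, transient ≥ steady total DE, late
injections (≥ 1.4 s) floating back out — emerge from the mechanics above;
none is asserted into the model.

## Numerical choices and degenerate inputs

* Equal-pressure split by exact recursion; a dense linear-system solve is
  kept as an independent oracle in the tests (agreement to 1e-9).
* The cosine inversions clamp their arguments to [-1, 1] and force event
  times monotone, guarding the grazing cases (injection exactly at a zero
  crossing, a bolus stalling exactly at a conduit end).
* A single-branch table (trachea only) is a legal degenerate tree: it may
  carry no lobe label, escapes are credited to `"none"`, and the
  single-region deposited fraction equals the correlation value exactly —
  the closed form the transport tests pin at 1e-12.
* A zero cut offset halves the tracheal disk; an offset equal to the
  radius degenerates to the full circle and is flagged with a warning.
* `lobar_fractions` with a zero-flow lobe leaves its boluses stationary;
  they end suspended rather than erroring.

## Problem sizes

The packaged analyses run the 127-branch tree with 401-snapshot cycles,
ten-injection sweeps and one 2720-particle Monte-Carlo run; the whole test
suite and the acceptance script each complete in well under a minute on a
single core. These sizes are the study conditions themselves — nothing is
scaled down from them.

## Known limitations

* No 3D flow features: laryngeal-jet structure, secondary vortices,
  cross-sectional velocity profiles and vorticity are out of scope, and
  exact 3D deposition percentages are not reproducible here; trends are.
* Quasi-steady flow neglects Womersley effects (justified at 0.25 Hz,
  wrong for rapid manoeuvres).
* Per-pass regional DE cannot resolve *where within* a region deposition
  lands (e.g. carinal hot spots).
* The characteristic fixture's anatomical realism ends at its design
  targets (ventilation partition, calibre progression); it is an
  emulation, not a cast.
* Ring geometry does not feed back on flow or deposition by default.
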