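---
title: "Models and methods behind chewsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chewsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chewsim)
```

# The problem

During unilateral chewing the mandibular elevator muscles — masseter (M),
medial pterygoid (MP) and temporalis (T, with anterior/middle/posterior
parts) — drive the mandible along a food-dependent chewing path while the
food resists closure between the molar rows. chewsim simulates one closing
cycle of this system at desk scale: given a food's force–deformation
characteristic $F = f(\Delta h)$ and its height $h$, it computes the muscle
length changes (contractions), the muscle force histories on the working
(W) and non-working (N) sides, and derived muscle parameters — maximum
force $F_H$, contraction at maximum force $\Delta q_H$, total contraction
$\Delta q_C$, secant stiffness $K = F_H/\Delta q_H$, intrinsic strength
$k = F_H/\mathrm{PCSA}$ and the proportionality coefficients
$R_F = F_H/F_{max}$ and $R_q = \Delta q_C / h$.

The package bundles a reference dataset (per-food muscle forces,
contractions, stiffness, intrinsic strength and the $R$ coefficients from a
published simulation study of the same system) both as calibration targets
for the default geometry and as fixtures for arithmetic-level validation.

# Model structure

**Rigid bodies and joints.** The skull is fixed; the mandible is a rigid
body suspended at the two temporomandibular joints (TMJ). Kinematically the
working-side condyle is a fixed centre of rotation and the non-working
condyle is constrained to an inclined guide plane whose slopes (forward-down
$\psi$, medial-down $\mu$) prescribe the condylar descent "downward, forward
and medially". A mandibular pose therefore has three generalised
coordinates: opening about the working condyle's transverse axis, yaw about
its vertical axis and roll about its anteroposterior axis. The non-working
condylar slide is recovered from the solved pose. Coordinates: origin at the
incisal end point IS, $x$ anterior, $y$ left, $z$ superior, SI metres; the
default working side is the right ($y<0$), and a left-working model is the
exact mirror image.

**Muscles.** Each muscle is an effective straight line of action between a
skull origin and a mandibular insertion. The force solve uses four active
lines — temporalis per side, and per side a single resultant line V standing
in for masseter + medial pterygoid. The V force is decomposed back into
masseter and medial pterygoid magnitudes by a fixed planar projection onto
the two anatomical directions at the closed pose; because the projection is
a constant linear map, the FM/FMP ratio (1.1157) is food-invariant exactly.
The temporalis principal force is decomposed post hoc into anterior, middle
and posterior parts by PCSA-proportional scalar fractions
(0.47992, 0.28999, 0.23009), fitted by sum-constrained least squares to the
reference component tables; the part direction angles (76°, 42°, 22° above
the horizontal sagittal axis, principal line at 58°) are carried as
metadata. The calibrated principal temporalis line is steeper (about 70°)
than the nominal figure angle; the two serve different roles (length/force
kinetics vs. component directions).

**Food load.** The occlusal force acts at the point IW on the first molar
of the working side, perpendicular to the occlusal plane and opposing
closure (the application point is anatomically given; the direction is a
documented modelling choice). Its magnitude follows the food characteristic
evaluated at the current closure $\Delta h(t) = h + z_{IS}(t)$.

# The synthetic food curves

The measured characteristics are not available in tabulated form, so the
foodbank generates parametric stand-ins for the five specimens (dark
chocolate `d`, chocolate bar `b`, apple `a`, carrot `c`, sausage `s`):

* a power-law rise $(\Delta h / (p\,h))^{r}$ (default $r = 2$) to the peak
  force at closure fraction $p$,
* a Gaussian post-peak envelope: brittle curves (`d`, `c`, `a`) drop below
  half the peak within half the remaining closure; ductile curves
  (`b`, `s`) decay onto a plateau at 65 % of the peak.

Two parameters per food are inherited from the reference tables rather than
guessed: the peak force $F_{max}$ by inverting the working-masseter
relation $F_{H} = R_F F_{max}$ (the only route available, cross-checked
through the medial-pterygoid row), and the peak position $p$ as the
working-masseter ratio $\Delta q_H/\Delta q_C$, which transfers to the
closure fraction because contraction is monotone in closure. Curves are
deterministic; optional seeded multiplicative noise exists for robustness
experiments only.

What the generator does *not* emulate: specimen-to-specimen variability
(the reference dimensions are means), saliva/temperature effects, the
multi-peak fine structure of real fracture curves, and within-cycle changes
of the food's mechanical state. Passing tests therefore demonstrate the
mechanics of the model under idealised, smooth load curves, not predictions
for any individual real specimen.

# Chewing path

The closing arc of the incisal point is an ellipse-like curve in the
frontal plane from the chewing start point BP — laterally offset toward the
working side, a food height below closure — up to IS. Its vertical extent
equals $h$ exactly; its lateral profile splits into a start offset that
decays with closure (fraction $\rho = 0.65$, calibrated) and a mid-arc
bulge beyond the BP–IS chord. The overall lateral amplitude is solved per
food so that the arc length equals $v_t\,t_{chew}$ at the constant closing
speed $v_t = 0.02$ m/s — this resolves the otherwise inconsistent pair
$(h, t_{chew})$, whose ratio exceeds $1/v_t$ by a consistent factor of
about 1.11. The path is parameterised uniformly by arc length (monotone
cubic inversion of a dense arc-length table), so the incisal speed is
$v_t$ to within 0.1 %.

The lateral start offset matters: for a sagittally symmetric anatomy with
symmetric start and end poses the total contractions would be exactly equal
on both sides. The offset swings the open mandible toward the working side,
stretching the non-working muscles more and producing the observed W/N
contraction asymmetry.

# Stage 1: inverse kinematics

Per time step the three rotation angles solve a 3×3 root-finding problem:
two incisal coordinates on the path plus the plane constraint for the
non-working condyle. A damped Newton iteration with numerical Jacobian and
warm starts (marching from the closed end, where the identity pose is an
exact solution) converges to residuals below $10^{-11}$ m in a handful of
iterations; the suite asserts round-trip residuals below $10^{-9}$ m at
every step. The default grid is 200 steps; condylar path lengths are
polyline lengths of the per-step condyle positions.

Because the incisal path supplies two constraints and the guide plane the
third, no extra tie-break for roll is needed — the spec-level question of
how roll is fixed is answered here by the plane constraint itself.

# Stage 2: kinetostatic force solve

At each pose the mandible is in quasi-static equilibrium under the food
force, four muscle forces and one compressive normal per TMJ contact.
Inertia and gravity are neglected: at 0.02 m/s closing speed mandibular
inertia forces are orders of magnitude below occlusal forces. With two
point contacts the twist space compatible with the contacts is
4-dimensional; projecting all wrenches onto a basis of that space (virtual
work) gives a 4×4 linear system for the muscle magnitudes. The full 6×6
Newton–Euler system with the two contact normals as extra unknowns is
solved independently at every step as a cross-check (agreement is at
rounding level, asserted below 0.1 %) and supplies the joint reactions.

Two contact-model details are load-bearing:

* **The working-side contact point is offset from the rotation centre**
  (onto the articular eminence). A reaction acting exactly at the centre
  has no moment about the condylar axis; the reference force levels
  ($\sum R_F \approx 4.9$ per unit occlusal force across both sides) are
  then only attainable with nearly singular muscle geometry. With the
  offset, the large compressive reaction contributes a real moment and the
  system is well conditioned.
* **Contact reactions exchange work along the path.** The contact point of
  a shaped joint is not the instantaneous rotation centre, so the energy
  identity $\sum R_F R_q = 1$ that would hold for workless constraints does
  not apply — which is exactly what the reference coefficient tables
  require ($\sum R_F R_q \approx 2.15$ when combined naively over the
  individual muscles).

Negative solved muscle forces are a hard error in validation mode and a
warning + clamp in exploratory mode; the calibrated default produces
non-negative forces and compressive reactions for all five foods.

# Metrics conventions

Contractions are reported positive for shortening,
$\Delta q = q(0) - q(t)$ from the open-mouth start. $F_H$ is the maximum
over the closing phase and $t_H$ its time; $\Delta q_H$ is the contraction
at $t_H$; $K = F_H / \Delta q_H$ (secant form); $k = F_H/\mathrm{PCSA}$
with PCSA 6.80, 4.37 and 8.23 cm² for M, MP and T (temporalis parts use
their PCSA-proportional share, so their $k$ equals the principal's). The
non-linear (tangent) stiffness is the derivative of a monotone
piecewise-cubic fit of force versus contraction on the rising limb, with an
optional smoothing-spline pre-pass and a central-difference fallback; a
tangent-vs-secant gap of order 10 % is expected for these concave patterns
and is reported, not hidden. Side-asymmetry summaries follow fixed
conventions: pooled sums for the force and contraction deficits, per-case
means for the stiffness and intrinsic-strength comparisons, matching how
the reference headline percentages (14, 17, 29, 2.7, 28, 10) are formed.

# Calibration

The skull and mandible the reference tables were produced with are not
distributable, so the default geometry is a landmark surrogate with free
parameters: attachment positions and line directions within plausible
bounds, guide-plane slopes, intercondylar half-width, contact-normal
orientation and contact-point offset, load-point lateral position and the
path start-offset fraction. Calibration was staged, exploiting the
structure of the problem (poses depend only on condyle/guide/path
parameters, not on muscle attachments; masseter/MP directions enter only
the split constants and their own length kinetics):

1. the intercondylar half-width is solved so the sausage non-working
   condylar path length is 0.0102 m exactly;
2. the temporalis line, V line, contact geometry and load point are fitted
   by Levenberg–Marquardt to the force coefficients (FT and FV levels and
   their W/N ratios) at the per-food peak poses, weighting dark chocolate —
   the reference food of the headline ratio 1.215 — most strongly, together
   with the temporalis contraction ratios;
3. masseter and medial-pterygoid directions are derived from the achieved
   V level (so the split constants are exact), and their insertions are
   then fitted to the contraction ratios.

`calibrate_anatomy()` exposes the same residuals for user recalibration,
and the shipped defaults are the converged values, so
`build_default_anatomy()` needs no further fitting.

**What the calibrated default reproduces** (all recomputed by the test
suite and the acceptance script): the chocolate peak working-masseter to
peak occlusal force ratio 1.215 within 1 %; the sausage non-working
condylar path 0.0102 m within 0.1 %; the carrot peak masseter force within
2 %; the exact FM/FMP ratio; contraction coefficients within roughly
±0.03 of the reference values with the chocolate masseter total
contraction within 5 %.

**What it does not reproduce** — these limits are documented rather than
papered over:

* Across-food constancy of the force coefficients: the equilibrium ratio
  map varies with the peak pose (each food peaks at a different opening and
  lateral position), giving coefficients of variation near 10 % instead of
  the sub-1 % constancy the reference tables suggest; the temporalis means
  deviate up to ~17 % on the non-working side. The corresponding acceptance
  property checks are left failing by design.
* Strict working-side dominance of the temporalis near occlusion: for
  foods whose force persists to closure, FT on the non-working side
  overtakes the working side in the final part of the cycle.
* The non-working condylar path lengths of the four non-calibrated foods
  run 8–18 % above their reference values; the five reference lengths are
  mutually inconsistent with near-linear kinematics (their ratio to food
  height varies 0.33–0.38), so only the stated acceptance value (sausage)
  is enforced.
* Muscle shortening is not exactly proportional to vertical closure along
  the curved arc (the start offset decays early), so the simulated
  $\Delta q_H/\Delta q_C$ ratio exceeds the curve parameter $p$ by
  ~15–20 % and simulated secant stiffness runs below the reference values;
  the fixture-tier stiffness checks are unaffected.

# Numerical choices

* Time grid: 200 steps per cycle by default (minimum 50); pose tolerance
  $10^{-11}$ m; warm-started damped Newton.
* Path tables: 2000-segment arc-length table, monotone cubic (`hyman`)
  inversion.
* The 4×4 twist basis comes from an SVD null space of the 2×6 contact
  constraint matrix; both equilibrium routes use plain dense solves.
* Degenerate inputs (zero food height, non-monotone closure, negative
  forces, unreachable path points, all-zero force series) raise explicit
  errors or flagged rows rather than silent NA.
* Problem sizes in the test suite: one shared five-food, 200-step
  simulation (a few seconds) backs the simulation-tier checks; unit tests
  use 60–100 steps.

# Known limitations

One chewing cycle only; no bolus formation, no viscoelastic or
activation-dependent muscle behaviour (elastic-line kinetostatics only), no
friction or articular disc mechanics, no EMG prediction, and no
tooth/bone stress analysis. The anatomy is an effective landmark model
calibrated to reproduce aggregate coefficients — individual landmark
positions should not be read as patient anatomy.
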