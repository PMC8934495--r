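---
title: "Quasi-static shoulder simulation: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-static shoulder simulation: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`shouldersim` compares three configurations of the human shoulder — the
natural gleno-humeral joint (NS), a reverse shoulder prosthesis (RSP), and a
dual-bearing glenoid-sparing prosthesis with two offset centres of rotation
(DBSP) — by simulating four arm motions under a 2 kg hand load and
resolving, at every pose, the muscle forces and the gleno-humeral joint
reaction force (JRF). This vignette is the package's own account of the
model, its assumptions, the tunable parameters and the numerical choices.

## The quasi-static model

The skeleton is a rigid-body tree rooted at the thorax: head, clavicle,
scapula, humerus, ulna, radius and hand, connected by fixed, hinge, gimbal
and ball joints. Motion is slow enough that inertial forces are negligible
("quasi-static"): a noisy capture timeline is made quasi-static by
multiplying its timestamps by 1000 (`time_stretch()`), which divides implied
accelerations by $10^6$ without filtering the samples. At every time step the
generalized muscle-and-reserve torques must balance gravity exactly:

$$ R(q)\,\mathrm{diag}(f)\,a + s = \tau(q), \qquad 0 \le a_i \le 1 , $$

where $R$ is the matrix of tendon-excursion moment arms
($r = -\partial L/\partial q$, central finite differences of the wrapped
path length), $f_i = F^{max}_i\,f_L(\ell_i/\ell^{opt}_i)$ is each element's
activation-to-force gain under a rigid-tendon Hill model with the
force-velocity factor fixed at 1, $\tau = -\partial V/\partial q$ are the
gravity torques from the principle of virtual work, and $s$ are idealised
reserve torques. Muscle redundancy is resolved by **static optimization**:

$$ \min_a \; \sum_i a_i^2 \;+\; w_r \sum_j (s_j/g_j)^2 , $$

a strictly convex box-constrained quadratic program solved exactly by a
primal active-set method written in the package. Eliminating $s$ makes the
torque equality hold to machine precision by construction; the reported
equilibrium residual is $\le 10^{-6}$ N m at every step. The reserve penalty
weight $w_r = 10^4$ with gain $g_j = 1$ N m keeps reserve "leakage" below
about $10^{-4}$ N m when the muscles can carry the load; a step whose
largest reserve torque exceeds $10^{-3}$ N m is flagged
`infeasible_reserves_used` and kept, never dropped.

The JRF is a free-body Newton balance of the subtree distal to the reported
joint: gravity on the distal segments and point loads, plus the muscle
tension forces applied at attachments, eyelets and wrap contacts (a
frictionless wrap receives $-T(\hat u_1 + \hat u_2)$, the reaction of the
two tangent segments). For the DBSP the reported joint is the scapula–ring
fixed joint, i.e. the reaction between scapula and glenoid ring.

## The three configurations

All three variants share the same skeleton, muscle set, attachment
coordinates and muscle parameters; they differ only in the gleno-humeral
joint structure and the wrapping surface:

* **NS** — ball joint at the humeral head centre (10 mm lateral of the
  glenoid face), intrinsic Y-X-Y sequence (plane of elevation, elevation,
  axial rotation). The deltoid wraps a 48 mm humeral-head sphere.
* **RSP** — ball joint medialised onto the glenoid face, on the
  antero-posterior midline 18 mm above the inferior glenoid rim; the 36 mm
  glenosphere is inflated by half the deltoid thickness (10 mm) to a 56 mm
  spherical wrap. Supraspinatus deactivated.
* **DBSP** — five-joint assembly scapula → glenoid ring (fixed, tilted 10°
  downward) → PE bearing (hinge about the ring axis) → ball head (gimbal) →
  offset adapter (fixed) → humerus (fixed); 1 + 2 = 3 rotational DOF, like
  the ball joints, but with two centres of rotation offset 10 mm along the
  ring axis (the implant drawings do not dimension this offset; it is a
  declared assumption, exposed as `dual_cor_offset`). The 55 mm ring is
  inflated in-plane to a 75 × 75 × 28 mm ellipsoid wrap. Supraspinatus
  deactivated.

The seven studied muscle groups carry 4/4/7 deltoid elements (anterior,
middle, posterior) and 11/6/3/4 rotator-cuff elements (subscapularis,
infraspinatus, teres minor, supraspinatus). Group maximal isometric forces
are calibrated so that each group's summed $F^{max}$ matches the capacity
its published peak-force/activation ratio implies (e.g. infraspinatus
$\approx$ 1.44 kN, middle deltoid $\approx$ 1.17 kN), split evenly over the
elements. Optimal fibre and tendon slack lengths are set from the path
length at a 40° reference elevation ($\ell^{opt} = 0.8 L_{ref}$,
$\ell^{slack} = 0.2 L_{ref}$) so fibres operate near the plateau of the
force–length bell (a Gaussian $\exp(-((\ell/\ell^{opt}-1)/0.45)^2)$
truncated outside $[0.5, 1.5]$; the passive exponential toe curve exists
but is disabled by default, matching an activation-driven protocol).

**The geometry is synthetic.** Segment masses and lengths follow standard
adult anthropometry; attachment coordinates are plausible constructions
that reproduce the qualitative lines of action, not a cadaver dataset.
Absolute forces are therefore not comparable with measurements from
calibrated 138-element cadaver-parameter models; the package's claims are
the solver contracts (verified against independent oracles in the test
suite) and the direction of the NS/RSP/DBSP differences, not magnitudes.

## Motions and the synthetic-capture stage

Four motions, minimum-jerk profiles (zero endpoint velocity and
acceleration): abduction 0–120° (coronal plane), scaption 0–120° (plane
fixed 30° anterior to coronal — a common convention, chosen here because
the source protocol does not define the plane), internal rotation 0–40°
and external rotation 40–0° about the humeral long axis, starting with the
palm facing posterior. The protocol states the external rotation range
both as 0–40° and 40–0°; the default runs 40→0 and `er_reversed = FALSE`
selects the other direction. Elevation motions split the humero-thoracic
angle by a simplified 2:1 scapulo-humeral rhythm (scapular upward rotation
engages above 30°), a deliberate replacement for ellipsoid-gliding
scapulo-thoracic articulation models; the scapular coordinate is
kinematically driven and its torque absorbed by an ideal coordinate
actuator, mirroring driven scapulo-thoracic kinematics with added
actuators. Elevation motions are performed with a straight arm (the
standard abduction protocol); axial rotations with the elbow flexed 90°
(the clinical rotation posture), which also gives gravity a non-trivial
axial moment for the cuff to balance.

The synthetic-capture stage places nine surface markers (three each on
thorax, scapula, humerus), generates world trajectories by forward
kinematics at a nominal 100 Hz, adds i.i.d. Gaussian noise per axis
(deterministic given a seed; default 42), and recovers joint coordinates by
per-frame Gauss–Newton least squares on the analytic point Jacobian,
warm-started from the previous frame, with no smoothing filter — time
stretching, not filtering, is the quasi-static treatment. Round-trip
recovery is exact ($\le 10^{-6}$ rad) on noise-free markers and unbiased
(mean elevation error $< 0.2°$ over 100 seeds) at 2 mm noise.

The DBSP joints are driven through the same humeral motions by orientation
matching: a 3-coordinate Gauss–Newton solve of the hinge/gimbal angles that
reproduces the Y-X-Y target rotation of the humerus.

## Numerical choices, degeneracies and tie-breaks

* **Euler conventions.** The source material never states its axis
  conventions; the package fixes a right-handed frame (y up, x anterior,
  z lateral for a right shoulder) and the ISB-like Y-X-Y ball sequence, and
  documents rather than guesses the original. Y-X-Y is singular at 0°
  elevation (plane and axial rotations coincide); the driven trajectories
  are well-defined there, but marker-based identification of the
  plane/axial split is not, so IK studies evaluate at $\ge 20°$ elevation.
  The DBSP gimbal axes are chosen as (x, z): with the hinge about the
  tilted ring axis, the 10° tilt keeps the first and third axes separated
  at arm-down, and the sequence stays regular through 90° elevation.
* **Sphere wrapping** is exact: shortest tangent–arc–tangent route in the
  plane through the two endpoints and the centre. A segment that merely
  grazes the surface is reported unwrapped (tie-break), and the path length
  is continuous across the grazing boundary.
* **Ellipsoid wrapping** uses the sphere route in axis-scaled coordinates,
  mapped back to the surface through a 16-point on-surface polyline. An
  iterative shortest-path refinement seeded from this route exists in the
  internals (`refine = TRUE`) but is not used by the solver: paths passing
  near the implant disc centre have two locally-shortest routes around the
  strongly anisotropic surface, and an optimizer that hops between them
  across the $10^{-4}$ rad finite-difference step destroys the moment
  arms. The mapped route is unique, smooth and continuous in the
  endpoints, at the cost of being slightly longer than the true geodesic —
  an acceptable bias for a comparison study, applied identically at every
  pose.
* **Moment arms** use central differences with step $10^{-4}$ rad;
  coordinates that move all of a muscle's bodies rigidly (or none) are
  skipped analytically. A muscle endpoint strictly inside a wrap surface is
  an error naming the muscle and the surface.
* **QP tie-breaks.** The reserve-regularised objective is strictly convex,
  so the minimiser is unique; there are no ties to break. The active-set
  solver starts from $a = 0$ (always feasible) and terminates on exact KKT
  conditions.
* **Degenerate muscle geometry** (fibre length clamped at zero, or outside
  the active force-length range) yields zero gain with a warning rather
  than an error.

## Friction

The bearings are modelled frictionless. A conservative Coulomb bound
quantifies what this neglects: the friction moment of a spherical/annular
bearing is at most $\mu \cdot \mathrm{JRF} \cdot r$ with $r$ the outer
contact radius (18 mm RSP glenosphere radius; 27.5 mm DBSP ring outer
radius) and $\mu \le 0.05$ for UHMWPE on CoCr.
`friction_moment_ratio()` expresses this as a percentage of the
gleno-humeral joint moment; the acceptance script evaluates it at each
prosthesis model's own simulated peak-abduction JRF and peak gravitational
gleno-humeral moment. Because both the outer-radius bound and the
peak-JRF/peak-moment pairing are conservative (the two peaks need not
coincide in time), this ratio is an upper bound on the true contribution of
friction, and on this synthetic geometry it lands near the few-percent
mark rather than far below it.

## Problem sizes and what passing tests show

The default simulations use 25 time steps per motion (the test and
acceptance runs use 13, where the minimum-jerk profile is already resolved);
randomised property tests use on the order of $10^3$ random configurations
for kinematic invariants, 100 seeds for the IK bias study, and a $10^{-3}$
resolution activation grid for the QP oracle. Passing tests establish the
solver contracts — kinematics, wrapping, moment arms, equilibrium, JRF,
recovery — and the directional mechanics of the implant comparison
(medialisation increases the deltoid abduction lever; cuff load shifts to
the deltoid when the supraspinatus is removed). They do not establish
agreement of absolute forces with any particular subject or cadaver
dataset: the synthetic generator emulates marker capture of an idealised
subject, without soft-tissue artifact, subject-specific anthropometry,
co-contraction beyond the minimum-effort criterion, or the 22 further
muscle groups of the full upper-limb models (representable in the data
model but not carrying calibrated parameters).

## Known limitations

Single-surface wrapping per path segment (one wrap per implant); no
cylinder/torus wraps; no muscle–muscle collision; no activation dynamics,
fatigue or force–velocity dependence; no closed kinematic loops; no
contact, wear or dislocation mechanics; the DBSP dual-COR offset and the
synthetic attachment coordinates are declared assumptions, not anatomy.
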