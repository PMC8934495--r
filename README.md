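# shouldersim

Quasi-static musculoskeletal simulation comparing three configurations of
the human shoulder: the natural gleno-humeral joint (**NS**), a reverse
shoulder prosthesis (**RSP**, ball medialised onto the glenoid), and a
dual-bearing glenoid-sparing prosthesis (**DBSP**, a hinge + gimbal
assembly with two offset centres of rotation). The package is aimed at
biomechanics researchers and implant designers who want a self-contained,
fully testable R implementation of the standard simulation chain —
inverse kinematics → static optimization → joint reaction forces —
for desk-scale comparison studies of shoulder arthroplasty designs.

## The model

The skeleton is a rigid-body tree (thorax, head, clavicle, scapula,
humerus, ulna, radius, hand) with fixed/hinge/gimbal/ball joints, a 2 kg
point mass rigidly attached to the hand, and 39 Hill-type muscle elements
in the seven studied groups (deltoid 4/4/7; rotator cuff 11/6/3/4). Muscle
paths deflect over sphere and ellipsoid wrapping surfaces; moment arms are
tendon-excursion derivatives `r = -dL/dq`. Motion is quasi-static (a noisy
capture timeline is stretched by 1000 instead of filtered), so at every
pose the muscle redundancy is resolved by **static optimization**:

```
min  Σ a_i²  +  w_r Σ (s_j/g_j)²
s.t. R diag(f) a + s = τ(q),   0 ≤ a_i ≤ 1
```

a strictly convex box-constrained QP solved exactly by a primal active-set
method (`static_optimization()`). The gleno-humeral joint reaction force
(JRF) is a free-body Newton balance of the distal subtree, including wrap
contact forces; for the DBSP it is the reaction between scapula and glenoid
ring. Peak group forces, activations (Σ element peaks / Σ F_max) and JRFs
are aggregated into a comparison table of percent changes relative to NS.

The default geometry is **synthetic** (standard anthropometry, plausible
attachment coordinates): the solver contracts and the NS/RSP/DBSP
directional differences are the claims, not absolute force magnitudes. See
`vignette("shouldersim-methods")` for assumptions, parameters and
numerical choices.

## Worked example

```r
library(shouldersim)

ns  <- build_natural_shoulder()   # also: build_rsp(), build_dbsp()
ns
#> <shoulder_model> variant NS: 8 bodies, 7 joints (4 DOF),
#>   39 muscle elements, 1 wrap surfaces

sol <- solve_motion(ns, "ABD")    # abduction 0-120 deg, 2 kg in hand
summary(sol)
#> NS ABD: peak JRF 812.0 N, max reserve torque 9.51e-06 N m
#>               group peak_force_N activation
#> 1  anterior_deltoid         89.2       0.18
#> 2     infraspinatus          5.2       0.00
#> 3    middle_deltoid        593.2       0.51
#> 4 posterior_deltoid        117.8       0.07
#> 5     subscapularis        124.8       0.09
#> 6     supraspinatus         80.9       0.13
#> 7       teres_minor          0.0       0.00
```

The peak JRF of 812 N while elevating a 2 kg load is in the physiological
range reported for instrumented shoulders; the middle deltoid carries most
of the abduction moment (activation 0.51), with the supraspinatus
assisting. Reserve torques at the 1e-6 N m level mean the muscles balance
gravity essentially exactly. `plot(sol)` draws group force versus
elevation angle; `run_pipeline()` runs all variants and motions and
aggregates the comparison:

```r
pp <- run_pipeline(variants = c("NS", "RSP", "DBSP"),
                   motions = c("ABD", "SCP", "IR", "ER"))
pp$comparison      # percent changes vs the natural shoulder
```

The packaged summary fixture (`load_table1_fixture()`) carries the
published peak forces, activations and JRFs of the three configurations;
`headline_comparisons()` recomputes the study-level percentages from it:

```r
head(headline_comparisons(load_table1_fixture()), 4)
#>             quantity model motion value_N ns_value_N percent_change_from_ns
#> 1                JRF   RSP    ABD  1142.2     1054.0                      8
#> 2      deltoid_total  DBSP    ABD   621.2      758.7                    -18
#> 3 rotator_cuff_total  DBSP    ABD   257.7      401.7                    -36
#> 4                JRF  DBSP    ABD   957.5     1054.0                     -9
```

i.e. with the dual-bearing prosthesis the total deltoid peak force in
abduction is 18% lower and the total rotator cuff force 36% lower than in
the natural shoulder, at a 9% lower joint reaction force.

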