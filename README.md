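# mechwork

Internal, external and total mechanical work of treadmill running from 2-D
sagittal marker kinematics, with allometric scaling of the results and
their relationship to long-distance running performance.

## The problem

Runners spend mechanical energy in two distinguishable ways: lifting and
accelerating the body centre of mass (**external work**, `W_ext`) and
swinging the limbs back and forth relative to it (**internal work**,
`W_int`). Both can be measured from a single sagittal video of reflective
markers, and their sum per kilogram per metre is a determinant of the
energy cost of running. Comparing such per-kilogram quantities across
runners of different size is subtler than dividing by body mass: many
physiological quantities scale as `mass^b` with `b < 1`, so the package
also fits the allometric exponent from cohort data and re-expresses work
in `J kg^-b m^-1`.

The computation follows the classical energy-based partition. Per segment
(11-segment rigid model from nine sagittal markers per side),

    KE_r = 1/2 m (v_ap,r^2 + v_v,r^2) + 1/2 m K^2 w^2

is the kinetic energy relative to the body centre of mass; segment curves
are summed within each limb (allowing within-limb energy transfer) and the
positive increments of the five group curves, accumulated over an integral
number of strides, give `W_int`. The centre-of-mass energy

    E_CM = M g h + 1/2 M V_ap^2 + 1/2 M V_v^2

yields `W_ext` from its positive increments, and `W_tot = W_int + W_ext`
by König's theorem. The exponent `b` is the slope of `log y` on `log x`
(cohort body mass vs. absolute VO2max), and work–performance association
is summarised by Pearson correlations with least-squares prediction lines.

Everything is testable without recordings: a synthetic-data module
generates an analytic running gait whose true works are computed by a
10 kHz brute-force oracle, and cohorts with exact, constructed correlation
structure.

## Worked example

```r
library(mechwork)

# a 20 s treadmill run at 3.1 m/s, 240 Hz, 2 mm marker noise
p     <- gait_parameters(seed = 1)
gait  <- generate_gait(p)                      # 9 left-sagittal markers
model <- build_body_model(70, 1.71)            # 11 segments, Winter table

wk <- compute_work(gait$trajectories, model, n_strides = 5,
                   b_values = c(1, 0.75, 0.49))
print(wk)
#> Mechanical work over 5 stride(s) (3.571 s, 11.07 m, M = 70.0 kg)
#>   W_int = 253.71 J, W_ext = 649.23 J, W_tot = 902.94 J
#>   b = 1    : W_int 0.327, W_ext 0.838, W_tot 1.165 J kg^-b m^-1
#>   b = 0.75 : W_int 0.947, W_ext 2.423, W_tot 3.371 J kg^-b m^-1
#>   b = 0.49 : W_int 2.858, W_ext 7.314, W_tot 10.173 J kg^-b m^-1
```

The five strides are found automatically from the heel marker, each marker
is low-pass filtered at a residual-analysis cut-off clamped to 8–11 Hz,
and the unfilmed right side is reconstructed by a pelvis-anchored
half-stride delay. External work dominates (`W_int/W_ext` ≈ 39% for this
gait), and the absolute works divided by `M^b × distance` give the
normalised rows. Fitting the scaling exponent from a cohort:

```r
cohort <- generate_vo2_cohort(n = 14, b = 0.49, log_noise_sd = 0.03, seed = 1)
fit_allometric(cohort$body_mass_kg, cohort$vo2max_abs_ml_min)
#> Allometric fit: y = 178.6 * x^0.7124  (se_b = 0.0978, R^2 = 0.816, n = 14)
```

(a single n = 14 cohort estimates `b` with a standard error near 0.1;
`allometry_recovery()` certifies the estimator over 500 such cohorts).
The full chain — simulate, compute work, fit allometry, correlate with
performance — is laid out as numbered drivers under `analysis/`, each
writing its tables to `results/`.

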